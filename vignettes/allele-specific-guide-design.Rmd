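---
title: "Allele-specific guide design against passenger SNVs: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific guide design against passenger SNVs: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvguide)
```

## The model

`snvguide` selects somatic passenger single-nucleotide variants (SNVs) that
can serve as tumor-specific cleavage tags for SpCas9. The biological premise
is that disrupting an *essential* gene requires knocking out both copies,
while disrupting a *haploinsufficient* gene requires only one; a guide that
recognizes solely the mutant allele of such a gene therefore kills cells
carrying the SNV and spares cells that do not. The pipeline is a composition
of per-sample filters followed by sequence-level guide design and scoring;
each stage is a pure function of its inputs, so the whole run is
deterministic and order-independent.

### Clonality threshold

Passenger SNVs useful as therapeutic tags must be present in essentially
every tumor cell, i.e. they must have arisen early. The per-sample threshold

$$AF_{cut} = \mathrm{median}(hetAF) + \mathrm{MAD}(hetAF)$$

is computed over the heterozygous SNVs of the sample's *complete* QC-passed
mutation list (not the gene-class-filtered subset, which would bias the
median toward the handful of genes of interest). An SNV survives when its AF
is strictly greater than $AF_{cut}$. Two readings of the median's population
exist — heterozygous-only or all SNVs — and the heterozygous-only reading is
the default because it is the only fully specified one; the alternative is a
config switch (`af_median_population = "all"`). The MAD here is the literal
median absolute deviation (`mad_constant = 1`); R's normal-consistent scale
factor 1.4826 is available through the same knob, since analyses done in R
often inherit it silently. Samples with no heterozygous SNV have an
undefined threshold: they are skipped with a log entry and counted as
ineligible, never passed silently.

### Zygosity

Mutation tables rarely state zygosity. A genotype field, when present
(e.g. from a VCF), always wins. Otherwise a variant with AF ≥ 0.9 is called
homozygous — a loss-of-heterozygosity-tolerant heuristic; 0.9 clears clonal
homozygous variants at high purity while keeping clonal heterozygous
variants (AF near purity/2) safely below it. The decision path is stamped
into a `zygosity_source` column so downstream users can audit which rule
fired. Readers never guess: a MAF record always enters as `unknown`.

### Design-site enumeration

Spacer positions are numbered 1 (PAM-distal) to 20 (PAM-proximal). Two
placements discriminate alleles:

* `snv_in_seed`: the SNV falls at spacer positions
  $[21 - \text{seed\_window}, 20]$ (default window 12, i.e. positions 9–20)
  of a protospacer whose NGG PAM is intact on the mutant haplotype. The
  PAM-proximal seed is where single mismatches most reliably abolish Cas9
  cleavage, which is what protects the wild-type allele.
* `snv_in_pam`: the SNV itself completes an NGG PAM (PAM position 2 or 3)
  that the wild-type triplet lacks. The wild-type allele then has no
  cleavage-competent site at all.

An SNV at PAM position 1 (the N) is rejected: any base satisfies N, so the
placement cannot discriminate. SNVs that *destroy* a wild-type PAM would
make the wild-type allele targetable rather than the mutant and are out of
scope. Whether the published 12-bp rule meant the PAM-proximal spacer or a
window spanning both sides of the PAM is ambiguous; the spacer-seed reading
is implemented because it is the one the seed-specificity rationale
supports, and the window width is configurable for the other reading.

### Scoring and qualification

On-target efficiency sits behind a pluggable `on_target_scorer` interface.
The bundled default is a deliberate surrogate,
$\mathrm{clamp}(1 - 2\,|GC_{20} - 0.55|,\,0,\,1)$, rewarding the mid-high
spacer GC content characteristic of efficient guides. It is documented,
deterministic and monotone in GC distance — sufficient for exercising the
strict `> 0.5` cutoff and the pipeline plumbing — but it is *not* a trained
efficiency model; production users should plug an Azimuth-class scorer into
the same slot.

Off-target search is exact and exhaustive: every placement on both strands
matching the spacer at ≤ 3 mismatches with an NGG PAM is enumerated (no
heuristic index pruning — at the genome scales this package targets, a full
scan is fast and keeps the brute-force oracle equivalence trivial). Ambiguous
genomic bases never match. Each hit receives a CFD score: the product over
mismatched positions of a (position, spacer base, genomic base) penalty,
times a PAM-dinucleotide penalty; a perfect NGG match scores exactly 1. A
guide qualifies iff its on-target score is strictly above 0.5 **and** no
off-target CFD exceeds 0.175 (a hit at exactly 0.175 is tolerated; an
on-target score of exactly 0.5 is not).

Two deliberate exclusions from the disqualifying off-target set: the guide's
own protospacer locus (it would otherwise always self-match), and the
wild-type allele at that same locus. For seed designs the wild-type locus is
an unavoidable one-mismatch site whose CFD frequently exceeds 0.175;
counting it would disqualify exactly the guides the strategy is built on.
It is instead reported as `wt_allele_cfd` — a direct readout of predicted
allele discrimination — and a config flag (`count_wt_as_offtarget`) reverses
the choice for users who want the conservative behavior.

### CFD penalty table

The package ships a *synthetic* penalty model (`cfd_default_model()`) with
the structure of published CFD tables: matched bases score 1, mismatch penalties decay linearly from
PAM-distal (0.90) to PAM-proximal (0.05), transversions are penalized 20%
more than transitions, and `pam_penalty("GG") = 1` with small penalties for
near-cognate dinucleotides. Published tables load through
`read_cfd_model()` (TSV; RNA-keyed tables are re-keyed U→T). All
correctness tests hold for any table satisfying the structural invariants.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `qc_min_alt_reads` | 5 | minimum alt-supporting reads (inclusive) |
| `qc_min_af` | 0.20 | minimum AF at QC (inclusive) |
| `hom_af_min` | 0.9 | AF at which unknown zygosity becomes homozygous |
| `mad_constant` | 1.0 | MAD scale (1.4826 for R's convention) |
| `expression_min` | 1.0 | log2(FPKM+1) cutoff, strict `>` |
| `seed_window` | 12 | PAM-proximal spacer positions admitting the SNV |
| `pam_motifs` | NGG | IUPAC PAM set (e.g. add NAG for relaxed scanning) |
| `on_target_min` | 0.5 | on-target cutoff, strict `>` |
| `max_mismatches` | 3 | off-target mismatch budget |
| `off_target_max_cfd` | 0.175 | disqualify when strictly exceeded |

## The synthetic cohort generator

`generate_cohort()` emulates the pipeline's real inputs at desk scale. The
reference conditions are 5 contigs × 50 kb, 30 gene models (8 essential, 8
haploinsufficient, 4 oncogene, 10 other), 20 samples, ~25 background SNVs
each, purity 0.95 and 70% clonal mutations. Heterozygous clonal AFs follow a
Beta centered at 0.5 × purity (concentration 60), homozygous clonal AFs a
Beta near purity, subclonal AFs a Beta centered at 0.15; read depth is fixed
at 1000 so every AF is exactly `alt/1000` and files round-trip
byte-identically. Purity 0.95 was chosen so clonal homozygous variants
(AF ≈ 0.95) clear the 0.9 zygosity rule; planted heterozygous SNVs get
AF 0.80, above any realized $AF_{cut}$ (≈ 0.45–0.55 under these conditions)
yet below 0.9.

Planting is constructive: for each planted sample an engineered spacer
(GC 11/20, so the surrogate scores ≈ 1) is written into the genome with
either a TGG PAM (seed designs, SNV at spacer position 20) or a TGC
wild-type PAM whose SNV completes TGG (PAM designs). Background SNVs are
confined to oncogene/"other" genes, which the gene-class filter removes
wholesale — so the set of eligible samples equals the planted set *exactly*,
not just with high probability. The generator scrubs accidental ≤ 3-mismatch
near-matches to planted spacers and then verifies its own truth by running
the real filter/design/scoring stages on every planted SNV, aborting rather
than emitting a wrong truth file.

What the generator does **not** emulate: mutational signatures, germline
variation, copy-number change, tumor purity heterogeneity, and realistic
genome composition (repeats, GC skew). Passing end-to-end tests therefore
demonstrates the pipeline's logic and determinism, not calling performance
on real tumors.

## Numerical choices and degenerate inputs

* All coordinates are 1-based inclusive at every interface (MAF/VCF
  convention); BED-style exports convert explicitly.
* Ties: AF exactly at $AF_{cut}$ is dropped (strict `>`, configurable);
  expression exactly 1.0 is dropped; on-target exactly 0.5 is dropped;
  off-target CFD exactly 0.175 is kept.
* Medians use the midpoint rule for even-length vectors (R's default),
  matched by the brute-force sort-based oracle in the tests.
* Candidates whose 30-nt scoring context would run off a contig end are
  dropped with a counted reason — Azimuth-style scorers require the full
  context.
* Duplicate design placements are collapsed on (start, strand); report rows
  are sorted on (sample, chrom, pos, strand, spacer) so repeat runs are
  byte-identical.
* A sample with zero surviving SNVs — or zero heterozygous SNVs, making
  $AF_{cut}$ undefined — remains in every eligibility denominator.

## Problem sizes used in the test-suite

Oracle-equivalence checks run at 1,000 random instances each: AF vectors up
to length 75, 45–75-nt design contexts, and 2-kb genomes for the off-target
scan (sizes chosen so the deliberately naive brute-force oracles stay quick
while still exercising multi-contig, both-strand, 0–3-mismatch behavior).
The end-to-end acceptance cohort is the reference 20-sample, 5 × 50 kb
configuration above.

## Known limitations

* The bundled on-target scorer and CFD table are documented surrogates;
  absolute score values are not comparable to published trained models,
  though all cutoff logic is.
* Only SNV targets are supported — no InDel/MNP targets, no base- or
  prime-editor designs, no DNA/RNA-bulge off-target search.
* No tumor-purity or copy-number correction of AFs; clonality is handled
  entirely by the $AF_{cut}$ heuristic.
* Hotspot matching is by genomic position (with optional allele match), not
  by protein residue.
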