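# snvguide

Allele-specific CRISPR/Cas9 guide design against passenger SNVs in essential
and haploinsufficient genes.

## The problem

Most tumors carry few actionable oncogenic hotspot mutations, but thousands of
somatic passenger single-nucleotide variants (SNVs). When a passenger SNV sits
in a gene whose disruption kills the cell — an **essential** gene (homozygous
loss is lethal) or a **haploinsufficient** gene (losing one copy suffices) —
an SpCas9 guide that recognizes only the mutant allele can selectively
eliminate tumor cells while sparing normal tissue, which lacks the variant.
`snvguide` implements the complete in-silico selection workflow for this
strategy, from per-sample somatic mutation tables to a cohort-level
eligibility report, for computational cancer genomicists and CRISPR screen
designers.

## The method

For each patient sample the pipeline applies, in order:

1. **Variant QC** — keep SNVs with ≥ 5 alt-supporting reads, allele frequency
   (AF) ≥ 0.20, and no segmental-duplication / tandem-repeat /
   germline-database flags; an optional cohort-recurrence filter restricts to
   known somatic mutations.
2. **Zygosity and gene class** — genotype-derived zygosity wins; otherwise
   AF ≥ 0.9 calls a variant homozygous. Keep homozygous SNVs in essential
   genes and SNVs of any zygosity in haploinsufficient genes.
3. **Clonality threshold** — per sample,

   `AF_cut = median(hetAF) + MAD(hetAF)`

   over the heterozygous SNVs of the full QC-passed list; only SNVs with
   AF > AF_cut (early, clonal variants) survive.
4. **Expression** — keep SNVs whose gene has log2(FPKM + 1) > 1 in the same
   sample; a missing value is missing, not zero.
5. **Guide design** — enumerate every 23-nt protospacer+PAM window on both
   strands where the SNV either (a) falls in the PAM-proximal 12-nt seed of a
   protospacer with an intact NGG PAM (`snv_in_seed`), or (b) itself creates
   a new NGG PAM absent from the wild-type allele (`snv_in_pam`). An SNV on
   the unconstrained PAM `N` cannot discriminate alleles and is rejected.
6. **On-target score** — strict cutoff > 0.5, behind a pluggable scorer
   interface (a documented GC-content surrogate is bundled; an external
   Azimuth-style model can be plugged in).
7. **Off-targets** — exhaustive genome scan for sites matching the spacer at
   ≤ 3 mismatches with an NGG PAM; each hit is scored with the Cutting
   Frequency Determination (CFD) product model, and a guide is discarded if
   any off-target CFD exceeds 0.175. The wild-type allele at the guide's own
   locus is reported separately (`wt_allele_cfd`) rather than counted as an
   off-target.

A patient is **eligible** when at least one qualified guide remains. Cohort
summaries report pooled and cancer-type-averaged eligibility plus the overlap
with the hotspot-mutation strategy, and a T7E1 utility converts band
densities to NHEJ%: `NHEJ(%) = 100 × (1 − (1 − fraction_cleaved)^(1/2))`.

Every stage is testable offline: `generate_cohort()` builds a deterministic
synthetic genome + MAF + expression + catalog bundle with planted,
provably-eligible samples and a ground-truth JSON.

## Worked example

```r
library(snvguide)

bundle <- generate_cohort(synthetic_cohort_spec(seed = 7), "sim7")
res <- run_pipeline(bundle$paths$maf, bundle$paths$genome,
                    bundle$paths$gene_catalog, bundle$paths$expression,
                    hotspots = bundle$paths$hotspots, output_dir = "run7")
print(res)
#> snvguide pipeline run: 20 samples, 10 guide candidates, 10 qualified
#> Cohort eligibility: 3/20 samples eligible (15.0% pooled, 15.0% type-averaged); 5 (25.0%) hotspot carriers
#> Venn: both=1 only-passenger=2 only-hotspot=4 neither=13
```

The three eligible samples are exactly the three the generator planted
(`bundle$truth$eligible_samples`); each carries at least one qualified guide
in its planted essential/haploinsufficient gene. `run7/guide_report.tsv`
lists every candidate with spacer, PAM, strand, design class, on-target
score, off-target count, maximum off-target CFD and the qualification
verdict; `run7/eligibility.json` carries the full-precision summary.

```r
print(nhej_percent(60, 40))
#> T7E1: fraction cleaved 0.6000 -> NHEJ 36.754%
```

The same operations are available from a shell:

```sh
exec/snvguide simulate --seed 7 --out sim7
exec/snvguide run --maf sim7/cohort.maf --genome sim7/genome.fa \
  --gene-catalog sim7/gene_catalog.tsv --expression sim7/expression.tsv \
  --hotspots sim7/hotspots.tsv --out run7
exec/snvguide t7e1 --digested 60 --parent 40
```

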