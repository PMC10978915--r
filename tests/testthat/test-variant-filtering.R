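# QC, zygosity, gene-class, AF_cut, expression and recurrence filters.

test_that("qc_filter applies inclusive read/AF thresholds and exclusion flags", {
  cfg <- pipeline_config()
  snvs <- make_snvs(
    make_snv(pos = 1, af = 0.20, alt_reads = 5L),            # boundary: kept
    make_snv(pos = 2, af = 0.20, alt_reads = 4L),            # too few reads
    make_snv(pos = 3, af = 0.19, alt_reads = 50L),           # AF below 20%
    make_snv(pos = 4, af = 0.50, alt_reads = 50L, flags = "segdup"),
    make_snv(pos = 5, af = 0.50, alt_reads = 50L, flags = "tandem_repeat;other"),
    make_snv(pos = 6, af = 0.50, alt_reads = NA_integer_),   # vacuous read check
    make_snv(pos = 7, af = 0.50, alt_reads = 9L, flags = "benign_note")
  )
  kept <- qc_filter(snvs, cfg)
  expect_equal(kept$pos, c(1L, 6L, 7L))
})

test_that("call_zygosity applies the AF rule but never overrides a genotype", {
  cfg <- pipeline_config()
  snvs <- make_snvs(
    make_snv(pos = 1, af = 0.95, zygosity = "unknown"),
    make_snv(pos = 2, af = 0.58, zygosity = "unknown"),
    make_snv(pos = 3, af = 0.90, zygosity = "unknown"),      # boundary: >= 0.9
    make_snv(pos = 4, af = 0.60, zygosity = "homozygous")    # genotype wins
  )
  out <- call_zygosity(snvs, cfg)
  expect_equal(out$zygosity,
               c("homozygous", "heterozygous", "homozygous", "homozygous"))
  expect_equal(out$zygosity_source, c("af_rule", "af_rule", "af_rule", "genotype"))
})

test_that("gene-class filter keeps exactly hap x any-zygosity and essential x homozygous", {
  catalog <- make_catalog(gene_symbol = c("ESS1", "HAP1", "ONC1"),
                          gene_class = c("essential", "haploinsufficient",
                                         "oncogene"))
  combos <- expand.grid(gene = c("ESS1", "HAP1", "ONC1", "UNKNOWN"),
                        zyg = c("heterozygous", "homozygous"),
                        stringsAsFactors = FALSE)
  snvs <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i)
    make_snv(pos = i, gene = combos$gene[i], zygosity = combos$zyg[i])))
  kept <- filter_by_gene_class(snvs, catalog)
  expect_setequal(
    paste(kept$gene_symbol, kept$zygosity),
    c("HAP1 heterozygous", "HAP1 homozygous", "ESS1 homozygous"))
  expect_equal(kept$gene_class[kept$gene_symbol == "HAP1"][1],
               "haploinsufficient")
  expect_error(filter_by_gene_class(make_snv(zygosity = "unknown"), catalog),
               "zygosity")
})

test_that("compute_af_cut reproduces the hand case and the exact identity", {
  afs <- c(0.10, 0.20, 0.30, 0.40, 0.50)
  snvs <- do.call(rbind, lapply(seq_along(afs), function(i)
    make_snv(pos = i, af = afs[i], zygosity = "heterozygous")))
  thr <- compute_af_cut(snvs, pipeline_config())
  expect_equal(thr$af_median, 0.30)
  expect_equal(thr$mad_het, 0.10)
  expect_equal(thr$af_cut, 0.40)
  expect_identical(thr$af_cut - thr$af_median - thr$mad_het, 0)
  expect_equal(thr$n_het_used, 5L)

  # zero-deviation and singleton cases
  same <- do.call(rbind, lapply(1:4, function(i)
    make_snv(pos = i, af = 0.5, zygosity = "heterozygous")))
  expect_equal(compute_af_cut(same)$af_cut, 0.5)
  single <- make_snv(af = 0.37, zygosity = "heterozygous")
  expect_equal(compute_af_cut(single)$af_cut, 0.37)

  # no heterozygous SNVs: threshold undefined, classed error
  hom_only <- make_snv(af = 0.95, zygosity = "homozygous")
  expect_error(compute_af_cut(hom_only), class = "af_cut_undefined")
})

test_that("compute_af_cut honors the population switch and the MAD constant", {
  snvs <- make_snvs(
    make_snv(pos = 1, af = 0.30, zygosity = "heterozygous"),
    make_snv(pos = 2, af = 0.40, zygosity = "heterozygous"),
    make_snv(pos = 3, af = 0.50, zygosity = "heterozygous"),
    make_snv(pos = 4, af = 0.95, zygosity = "homozygous")
  )
  het <- compute_af_cut(snvs, pipeline_config(af_median_population = "het"))
  all_pop <- compute_af_cut(snvs, pipeline_config(af_median_population = "all"))
  expect_equal(het$af_median, 0.40)
  expect_equal(all_pop$af_median, 0.45)   # median of all four AFs
  expect_equal(all_pop$mad_het, het$mad_het)  # MAD always over het
  scaled <- compute_af_cut(snvs, pipeline_config(mad_constant = 1.4826))
  expect_equal(scaled$mad_het, 1.4826 * het$mad_het)
})

test_that("AF_cut equals the sort-based oracle on random vectors, and order never matters", {
  set.seed(42)
  for (rep in 1:50) {
    n_het <- sample(1:40, 1)
    n_hom <- sample(0:10, 1)
    het_afs <- round(runif(n_het, 0.05, 0.95), 4)
    hom_afs <- if (n_hom > 0) round(runif(n_hom, 0.9, 1), 4) else numeric(0)
    snvs <- do.call(rbind, c(
      lapply(seq_along(het_afs), function(i)
        make_snv(pos = i, af = het_afs[i], zygosity = "heterozygous")),
      lapply(seq_along(hom_afs), function(i)
        make_snv(pos = 1000 + i, af = hom_afs[i], zygosity = "homozygous"))))
    thr <- compute_af_cut(snvs, pipeline_config())
    orc <- oracle_af_cut(het_afs)
    expect_equal(thr$af_cut, orc$af_cut)
    shuffled <- snvs[sample(nrow(snvs)), ]
    expect_equal(compute_af_cut(shuffled, pipeline_config())$af_cut, thr$af_cut)
  }
})

test_that("filter_by_af uses a strict comparison with a configurable tie rule", {
  snvs <- make_snvs(make_snv(pos = 1, af = 0.41), make_snv(pos = 2, af = 0.40),
                    make_snv(pos = 3, af = 0.10))
  thr <- structure(list(sample_id = "S1", af_median = 0.3, mad_het = 0.1,
                        af_cut = 0.40, n_snvs_used = 5L, n_het_used = 5L),
                   class = "af_threshold")
  expect_equal(filter_by_af(snvs, thr)$pos, 1L)
  expect_equal(filter_by_af(snvs, thr, pipeline_config(af_strict = FALSE))$pos,
               c(1L, 2L))
})

test_that("expression filter is strictly > 1 and treats missing as missing", {
  expr <- make_expr(c("S1", "S1", "S1"), c("G_HIGH", "G_ONE", "G_ZERO"),
                    c(1.5, 1.0, 0))
  snvs <- make_snvs(make_snv(pos = 1, gene = "G_HIGH"),
                    make_snv(pos = 2, gene = "G_ONE"),
                    make_snv(pos = 3, gene = "G_ZERO"),
                    make_snv(pos = 4, gene = "G_ABSENT"))
  expect_equal(filter_by_expression(snvs, expr)$pos, 1L)
  keep_missing <- pipeline_config(keep_missing_expression = TRUE)
  expect_equal(filter_by_expression(snvs, expr, keep_missing)$pos, c(1L, 4L))
})

test_that("recurrence filter is an exact (chrom,pos,ref,alt) intersection", {
  snvs <- make_snvs(make_snv(pos = 10, ref = "G", alt = "A"),
                    make_snv(pos = 20, ref = "C", alt = "T"))
  cat_hit <- data.frame(chrom = "ctg1", pos = 10L, ref_allele = "G",
                        alt_allele = "A", stringsAsFactors = FALSE)
  expect_equal(recurrence_filter(snvs, cat_hit)$pos, 10L)
  expect_equal(nrow(recurrence_filter(snvs, cat_hit[0, ])), 0)
  expect_equal(recurrence_filter(snvs, NULL)$pos, c(10L, 20L))  # stage skipped
  # allele mismatch is not a hit
  cat_mis <- data.frame(chrom = "ctg1", pos = 10L, ref_allele = "G",
                        alt_allele = "T", stringsAsFactors = FALSE)
  expect_equal(nrow(recurrence_filter(snvs, cat_mis)), 0)
})

test_that("hotspot carrier annotation matches on gene+position and optional alleles", {
  hotspots <- data.frame(gene_symbol = c("ONC1", "ONC2"), chrom = "ctg1",
                         pos = c(100L, 200L), ref_allele = c(NA, "G"),
                         alt_allele = c(NA, "A"), stringsAsFactors = FALSE)
  carrier <- make_snv(pos = 100, gene = "ONC1")
  expect_true(annotate_hotspot_carrier(carrier, hotspots))
  non <- make_snv(pos = 150, gene = "ONC1")
  expect_false(annotate_hotspot_carrier(non, hotspots))
  # position match but allele mismatch when the entry specifies alleles
  allele_mismatch <- make_snv(pos = 200, gene = "ONC2", ref = "G", alt = "T")
  expect_false(annotate_hotspot_carrier(allele_mismatch, hotspots))
  allele_match <- make_snv(pos = 200, gene = "ONC2", ref = "G", alt = "A")
  expect_true(annotate_hotspot_carrier(allele_match, hotspots))
})
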