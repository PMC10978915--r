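# On-target surrogate, CFD model, off-target enumeration, wild-type allele
# scoring and qualification.

ctx30_with_gc <- function(gc) {
  spacer <- paste(c(rep("G", gc), rep("A", 20 - gc)), collapse = "")
  paste0("AAAA", spacer, "TGGAAA")
}

test_that("the GC surrogate scorer follows its closed form and is deterministic", {
  sc <- gc_surrogate_scorer()
  expect_equal(sc$score(ctx30_with_gc(11)), 1 - 2 * abs(11 / 20 - 0.55))
  expect_equal(sc$score(ctx30_with_gc(11)), 0.99999999999999989, tolerance = 1e-12)
  expect_equal(sc$score(ctx30_with_gc(1)), 0)   # GC 0.05 clamps to 0
  expect_equal(sc$score(ctx30_with_gc(20)), 1 - 2 * abs(1 - 0.55))
  expect_identical(sc$score(ctx30_with_gc(7)), sc$score(ctx30_with_gc(7)))
  expect_error(sc$score(paste0(strrep("A", 29), "N")), "ACGT")
})

test_that("CFD scoring is the literal product of table penalties", {
  model <- cfd_default_model()
  sp <- strrep("AC", 10)
  # perfect match: empty product times pam penalty
  expect_equal(cfd_score(sp, sp, "AGG", model), 1.0)
  expect_equal(cfd_score(sp, sp, "TGG", model), 1.0)
  expect_equal(cfd_score(sp, sp, "TAG", model),
               unname(model$pam["AG"]))
  # single mismatch at position 12 (spacer C -> site T)
  site <- sp; substr(site, 12, 12) <- "T"
  expect_equal(cfd_score(sp, site, "CGG", model),
               unname(model$mismatch["12:C:T"]))
  # two mismatches multiply
  site2 <- sp; substr(site2, 3, 3) <- "T"; substr(site2, 18, 18) <- "G"
  expect_equal(cfd_score(sp, site2, "TGG", model),
               unname(model$mismatch["3:G:T"] * model$mismatch["18:C:G"]))
  # unknown lookup is a named error
  broken <- model; broken$mismatch <- broken$mismatch[-1]
  bad_site <- sp; substr(bad_site, 1, 1) <- "C"
  if ("1:A:C" %in% names(model$mismatch) && !"1:A:C" %in% names(broken$mismatch)) {
    expect_error(cfd_score(sp, bad_site, "TGG", broken), "position=1")
  }
})

test_that("CFD bounds hold on random cases: [0,1], 1 iff perfect+NGG, monotone in mismatches", {
  set.seed(71)
  model <- cfd_default_model()
  for (rep in 1:100) {
    sp <- random_seq(20)
    k <- sample(0:4, 1)
    site <- sp
    pos <- if (k > 0) sort(sample(20, k)) else integer(0)
    for (p in pos) {
      substr(site, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                           substr(site, p, p)), 1)
    }
    pam <- paste0(sample(c("A", "C", "G", "T"), 1),
                  sample(c("GG", "AG", "TT"), 1))
    s <- cfd_score(sp, site, pam, model)
    expect_gte(s, 0); expect_lte(s, 1)
    is_perfect_ngg <- (k == 0) && substr(pam, 2, 3) == "GG"
    expect_identical(s == 1, is_perfect_ngg)
    # hand-multiplied oracle
    hand <- prod(vapply(pos, function(p)
      model$mismatch[paste(p, substr(sp, p, p), substr(site, p, p), sep = ":")],
      numeric(1))) * model$pam[substr(pam, 2, 3)]
    expect_equal(s, unname(hand))
    # adding one more mismatch never increases the score
    if (k < 20) {
      free <- setdiff(1:20, pos)
      p2 <- sample(free, 1)
      site2 <- site
      substr(site2, p2, p2) <- sample(setdiff(c("A", "C", "G", "T"),
                                              substr(site2, p2, p2)), 1)
      expect_lte(cfd_score(sp, site2, pam, model), s)
    }
  }
})

test_that("CFD model TSV round trip preserves penalties and re-keys RNA bases", {
  model <- cfd_default_model()
  d <- tempdir()
  mp <- file.path(d, "mm.tsv"); pp <- file.path(d, "pam.tsv")
  write_cfd_model(model, mp, pp)
  back <- read_cfd_model(mp, pp)
  expect_equal(back$mismatch[names(model$mismatch)], model$mismatch)
  expect_equal(back$pam[names(model$pam)], model$pam)
  # RNA-keyed table: U is re-keyed to T at load time
  mm <- utils::read.delim(mp, stringsAsFactors = FALSE)
  mm$spacer_base[mm$spacer_base == "T"] <- "U"
  utils::write.table(mm, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  rekeyed <- read_cfd_model(mp, pp)
  expect_equal(rekeyed$mismatch["5:T:G"], model$mismatch["5:T:G"])
})

test_that("off-target scan finds planted copies and respects the PAM gate", {
  set.seed(81)
  spacer <- random_seq(20)
  genome <- Biostrings::DNAStringSet(c(ctg1 = random_seq(4000)))
  planted <- plant_off_target_copy(genome, spacer, n_mismatches = 0,
                                   pam = "TGG", at = list(chrom = "ctg1",
                                                          start = 1000))
  hits <- enumerate_off_targets(spacer, planted$genome)
  hit <- hits[hits$start == 1000, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$n_mismatches, 0L)
  expect_equal(hit$cfd, 1.0)
  expect_equal(hit$strand, "+")
  # same site with a non-NGG PAM is invisible under the default motif
  g2 <- Biostrings::DNAStringSet(c(ctg1 = random_seq(4000)))
  p2 <- plant_off_target_copy(g2, spacer, 0, pam = "TGA",
                              at = list(chrom = "ctg1", start = 1000))
  h2 <- enumerate_off_targets(spacer, p2$genome)
  expect_false(any(h2$start == 1000 & h2$strand == "+"))
  # mismatch budget: a 2-mismatch copy is found with the right positions
  g3 <- Biostrings::DNAStringSet(c(ctg1 = random_seq(4000)))
  p3 <- plant_off_target_copy(g3, spacer, 2, pam = "AGG",
                              at = list(chrom = "ctg1", start = 2000))
  h3 <- enumerate_off_targets(spacer, p3$genome)
  found <- h3[h3$start == 2000, ]
  expect_equal(found$n_mismatches, 2L)
  expect_equal(found$mismatch_positions,
               paste(p3$record$mismatch_positions, collapse = ","))
})

test_that("the exclude interval removes the guide's own locus and only that", {
  set.seed(91)
  spacer <- random_seq(20)
  genome <- Biostrings::DNAStringSet(c(ctg1 = random_seq(3000)))
  g <- plant_off_target_copy(genome, spacer, 0, "TGG",
                             at = list(chrom = "ctg1", start = 500))$genome
  g <- plant_off_target_copy(g, spacer, 0, "TGG",
                             at = list(chrom = "ctg1", start = 1500))$genome
  all_hits <- enumerate_off_targets(spacer, g)
  expect_setequal(all_hits$start, c(500L, 1500L))
  excl <- enumerate_off_targets(spacer, g,
                                exclude = list(chrom = "ctg1", start = 500,
                                               end = 519))
  expect_equal(excl$start, 1500L)
})

test_that("off-target enumeration equals the naive full-scan oracle on random genomes", {
  set.seed(101)
  for (rep in 1:40) {
    mm_budget <- sample(0:3, 1)
    cfg <- pipeline_config(max_mismatches = mm_budget)
    contigs <- c(ctg1 = random_seq(1500), ctg2 = random_seq(800))
    spacer <- random_seq(20)
    # bias half the runs toward hits by planting a near-copy
    if (rep %% 2 == 0) {
      g <- Biostrings::DNAStringSet(contigs)
      pl <- plant_off_target_copy(g, spacer, sample(0:mm_budget, 1), "NGG",
                                  at = list(chrom = "ctg1", start = 700))
      contigs <- as.character(pl$genome)
      names(contigs) <- c("ctg1", "ctg2")
    }
    genome <- Biostrings::DNAStringSet(contigs)
    impl <- enumerate_off_targets(spacer, genome, cfg)
    orc <- oracle_offtargets(spacer, as.list(contigs), max_mm = mm_budget)
    expect_identical(hit_keys(impl), hit_keys(orc))
  }
})

test_that("raising the mismatch budget never shrinks the hit set", {
  set.seed(111)
  contigs <- c(ctg1 = random_seq(5000))
  genome <- Biostrings::DNAStringSet(contigs)
  spacer <- substr(contigs[["ctg1"]], 101, 120)  # guaranteed self-match
  prev <- -1L
  for (mm in 0:3) {
    hits <- enumerate_off_targets(spacer, genome,
                                  pipeline_config(max_mismatches = mm))
    expect_gte(nrow(hits), prev)
    prev <- nrow(hits)
  }
})

test_that("off-target hits are strand-mirrored on the reverse-complemented genome", {
  set.seed(121)
  contigs <- c(ctg1 = random_seq(3000))
  spacer <- random_seq(20)
  g <- plant_off_target_copy(Biostrings::DNAStringSet(contigs), spacer, 1,
                             "TGG", at = list(chrom = "ctg1", start = 900))
  fwd <- enumerate_off_targets(spacer, g$genome)
  L <- nchar(as.character(g$genome[["ctg1"]]))
  grc <- Biostrings::DNAStringSet(c(ctg1 = rc(as.character(g$genome[["ctg1"]]))))
  rev <- enumerate_off_targets(spacer, grc)
  expect_equal(nrow(fwd), nrow(rev))
  key_fwd <- sort(paste(fwd$site_seq, fwd$n_mismatches, fwd$strand))
  key_rev <- sort(paste(rev$site_seq, rev$n_mismatches,
                        ifelse(rev$strand == "+", "-", "+")))
  expect_identical(key_fwd, key_rev)
  expect_setequal(L - rev$end + 1, fwd$start)
})

test_that("score_wt_allele: 0 without a wild-type PAM, CFD of the seed mismatch otherwise", {
  model <- cfd_default_model()
  sp_mut <- strrep("GA", 10)
  # snv_in_pam design: wild-type triplet is not NGG -> no cleavable site
  expect_equal(score_wt_allele(sp_mut, sp_mut, "TGC", model), 0)
  # snv_in_seed design: single mismatch at position 20
  sp_wt <- sp_mut; substr(sp_wt, 20, 20) <- "C"
  expect_equal(score_wt_allele(sp_mut, sp_wt, "TGG", model),
               unname(model$mismatch["20:A:C"]))
  # degenerate identical placement: score 1 with an integrity warning
  expect_warning(one <- score_wt_allele(sp_mut, sp_mut, "TGG", model),
                 "discriminate")
  expect_equal(one, 1.0)
})

test_that("qualification implements the published rule over all score combinations", {
  cfg <- pipeline_config()
  combos <- expand.grid(on = c(0.4, 0.5, 0.6),
                        off_state = c("none", "low", "tie", "high"),
                        stringsAsFactors = FALSE)
  cand <- data.frame(
    on_target_score = combos$on,
    n_off_targets = ifelse(combos$off_state == "none", 0L, 1L),
    max_off_target_cfd = c(none = NA, low = 0.10, tie = 0.175,
                           high = 0.30)[combos$off_state]
  )
  out <- qualify_guides(cand, cfg)
  # only on-target strictly > 0.5 AND (no hits OR max CFD <= 0.175) qualifies
  expected <- combos$on > 0.5 &
    (combos$off_state %in% c("none", "low", "tie"))
  expect_equal(out$qualified, expected)
  # permuting rows permutes verdicts identically (pure function)
  perm <- sample(nrow(cand))
  expect_equal(qualify_guides(cand[perm, ], cfg)$qualified, expected[perm])
  # tightening the CFD cutoff never grows the qualified set
  tighter <- qualify_guides(cand, pipeline_config(off_target_max_cfd = 0.05))
  expect_true(all(!out$qualified | out$qualified >= tighter$qualified))
  expect_true(all(tighter$qualified <= out$qualified))
})
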