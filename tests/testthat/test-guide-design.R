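# Context extraction and allele-discriminating design-site enumeration.

toy_genome <- function(seqs) Biostrings::DNAStringSet(seqs)

test_that("extract_context builds matched wt/mut windows and checks the reference", {
  set.seed(11)
  contig <- random_seq(200)
  substr(contig, 100, 100) <- "G"
  genome <- toy_genome(c(ctg1 = contig))
  snv <- make_snv(pos = 100, ref = "G", alt = "A")
  ctx <- extract_context(genome, snv, radius = 30)
  expect_equal(nchar(ctx$wt_context), 61)
  expect_equal(ctx$snv_offset, 31)
  expect_false(ctx$truncated)
  diffs <- which(strsplit(ctx$wt_context, "")[[1]] !=
                   strsplit(ctx$mut_context, "")[[1]])
  expect_equal(diffs, 31)
  expect_equal(substr(ctx$mut_context, 31, 31), "A")

  # truncation near the contig start is flagged
  substr(contig, 10, 10) <- "G"
  genome <- toy_genome(c(ctg1 = contig))
  ctx2 <- extract_context(genome, make_snv(pos = 10, ref = "G", alt = "C"),
                          radius = 30)
  expect_true(ctx2$truncated)
  expect_equal(ctx2$snv_offset, 10)

  # stale coordinates: genome base != ref_allele
  expect_error(extract_context(genome, make_snv(pos = 100, ref = "T", alt = "C")),
               "reference mismatch")
})

test_that("an SNV completing an NGG PAM yields an snv_in_pam site; the PAM N never discriminates", {
  # protospacer (20 A/C mix) + PAM; SNV converts wild-type TGC -> TGG at PAM
  # position 3 on the plus strand
  spacer <- strrep("CA", 10)
  wt <- paste0("AAAA", spacer, "TGC", "AAAA")
  snv_offset <- 4 + 20 + 3  # the C of TGC
  mut <- wt
  substr(mut, snv_offset, snv_offset) <- "G"
  sites <- find_design_sites(wt, mut, snv_offset)
  plus <- sites[sites$strand == "+", ]
  expect_equal(nrow(plus), 1)
  expect_equal(plus$design_class, "snv_in_pam")
  expect_equal(plus$snv_position_in_spacer, 0L)
  expect_equal(plus$spacer_mut, spacer)
  expect_identical(plus$spacer_mut, plus$spacer_wt)  # discrimination via PAM
  expect_equal(plus$pam_mut, "TGG")
  expect_equal(plus$pam_wt, "TGC")

  # SNV on the PAM N (position 1) is rejected even though mut has NGG
  wt_n <- paste0("AAAA", spacer, "CGG", "AAAA")
  off_n <- 4 + 20 + 1
  mut_n <- wt_n
  substr(mut_n, off_n, off_n) <- "T"
  sites_n <- find_design_sites(wt_n, mut_n, off_n)
  expect_false(any(sites_n$design_class == "snv_in_pam" & sites_n$strand == "+"))
})

test_that("seed placement honors the 12-bp window: position 15 accepted, position 5 rejected", {
  set.seed(21)
  # SNV at spacer position 15 of a plus-strand protospacer with TGG PAM
  spacer_mut <- "ACACACACACACACTCACAC"
  left <- "TTTT"; right <- "TTTT"
  mut <- paste0(left, spacer_mut, "TGG", right)
  snv_offset <- 4 + 15
  wt <- mut
  substr(wt, snv_offset, snv_offset) <- "G"  # wild-type base differs
  sites <- find_design_sites(wt, mut, snv_offset)
  hit <- sites[sites$strand == "+" & sites$ctx_proto_start == 5, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$design_class, "snv_in_seed")
  expect_equal(hit$snv_position_in_spacer, 15L)
  expect_equal(hit$spacer_mut, spacer_mut)

  # same geometry but SNV at spacer position 5: PAM-distal, excluded
  snv_offset5 <- 4 + 5
  wt5 <- mut
  substr(wt5, snv_offset5, snv_offset5) <- "G"
  sites5 <- find_design_sites(wt5, mut, snv_offset5)
  expect_false(any(sites5$strand == "+" & sites5$ctx_proto_start == 5))
  # widening the window via config admits it
  sites5w <- find_design_sites(wt5, mut, snv_offset5,
                               pipeline_config(seed_window = 16))
  expect_true(any(sites5w$strand == "+" & sites5w$ctx_proto_start == 5 &
                    sites5w$snv_position_in_spacer == 5))
})

test_that("find_design_sites equals the exhaustive window oracle on random instances", {
  set.seed(31)
  cfg <- pipeline_config()
  n_nonempty <- 0
  for (rep in 1:300) {
    L <- sample(40:80, 1)
    mut <- random_seq(L)
    off <- sample(seq(5, L - 4), 1)
    ref <- substr(mut, off, off)
    wt <- mut
    substr(wt, off, off) <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    sites <- find_design_sites(wt, mut, off, cfg)
    expect_identical(site_keys(sites), oracle_design_sites(wt, mut, off))
    if (nrow(sites) > 0) n_nonempty <- n_nonempty + 1
  }
  expect_gt(n_nonempty, 50)  # the comparison exercised real sites
})

test_that("every emitted site discriminates the alleles structurally", {
  set.seed(41)
  for (rep in 1:100) {
    mut <- random_seq(61)
    off <- 31
    wt <- mut
    ref <- substr(mut, off, off)
    substr(wt, off, off) <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    sites <- find_design_sites(wt, mut, off)
    if (nrow(sites) == 0) next
    expect_true(all(sites$spacer_mut != sites$spacer_wt |
                      sites$pam_mut != sites$pam_wt))
    expect_true(all(nchar(sites$spacer_mut) == 20))
    expect_true(all(nchar(sites$pam_mut) == 3))
    expect_true(all((sites$design_class == "snv_in_pam") ==
                      (sites$snv_position_in_spacer == 0)))
    seed_sites <- sites[sites$design_class == "snv_in_seed", ]
    expect_true(all(seed_sites$snv_position_in_spacer >= 9 &
                      seed_sites$snv_position_in_spacer <= 20))
  }
})

test_that("build_candidates assembles the 30-nt context and genome coordinates", {
  set.seed(51)
  contig <- random_seq(300)
  # plant plus-strand seed design: spacer at 101..120, SNV at spacer pos 20
  # (genome pos 120), PAM TGG at 121..123
  spacer_wt <- "ACGTACGTACGTACGTACGA"
  substr(contig, 101, 120) <- spacer_wt
  substr(contig, 121, 123) <- "TGG"
  genome <- toy_genome(c(ctg1 = contig))
  snv <- make_snv(pos = 120, ref = "A", alt = "C", zygosity = "homozygous")
  cand <- build_candidates(genome, snv)
  hit <- cand[cand$strand == "+" & cand$proto_start == 101, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$proto_end, 120)
  expect_equal(hit$spacer, "ACGTACGTACGTACGTACGC")  # mutant allele in spacer
  expect_equal(hit$spacer_wt, spacer_wt)
  expect_equal(hit$pam, "TGG")
  # context30 layout: 4 upstream + spacer + PAM + 3 downstream
  expect_equal(nchar(hit$context30_mut), 30)
  expect_equal(substr(hit$context30_mut, 5, 24), hit$spacer)
  expect_equal(substr(hit$context30_mut, 25, 27), hit$pam)
  expect_equal(substr(hit$context30_mut, 1, 4), substr(contig, 97, 100))
  # the emitted spacer re-extracts from the mutant haplotype at its coordinates
  mut_contig <- contig
  substr(mut_contig, 120, 120) <- "C"
  expect_equal(substr(mut_contig, hit$proto_start, hit$proto_end), hit$spacer)
})

test_that("design is strand-symmetric under genome reverse complement", {
  set.seed(61)
  for (rep in 1:20) {
    contig <- random_seq(240)
    pos <- sample(60:180, 1)
    ref <- substr(contig, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    genome <- toy_genome(c(ctg1 = contig))
    snv <- make_snv(pos = pos, ref = ref, alt = alt)
    cand_fwd <- build_candidates(genome, snv)

    L <- nchar(contig)
    genome_rc <- toy_genome(c(ctg1 = rc(contig)))
    snv_rc <- make_snv(pos = L - pos + 1,
                       ref = rc(ref), alt = rc(alt))
    cand_rc <- build_candidates(genome_rc, snv_rc)
    # same spacers, strands swapped, coordinates mirrored
    key_fwd <- sort(paste(cand_fwd$spacer, cand_fwd$strand))
    key_rc <- sort(paste(cand_rc$spacer,
                         ifelse(cand_rc$strand == "+", "-", "+")))
    expect_identical(key_fwd, key_rc)
    if (nrow(cand_fwd) > 0) {
      mirrored_start <- sort(L - cand_rc$proto_end + 1)
      expect_equal(sort(cand_fwd$proto_start), mirrored_start)
    }
  }
})
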