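test_that("GC content weights IUPAC positions by their G/C share", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("AYGT"), 0.375)
  expect_equal(gc_content("SSSS"), 1)   # S = C/G
  expect_error(gc_content("ACXG"), "invalid IUPAC")
  # equals the mean GC of the degenerate expansions
  for (p in c("AYGT", "ASDN", "RYSWKM")) {
    expect_equal(gc_content(p), mean(sapply(expand_degenerate(p), gc_content)))
  }
})

test_that("melting temperatures match the Wallace rule and a reference NN value", {
  expect_equal(suppressWarnings(melting_temperature("AAAA", "wallace")), 8)
  expect_equal(suppressWarnings(melting_temperature("GGGG", "wallace")), 16)
  # frozen reference value from an independent nearest-neighbor
  # implementation (same unified parameters, 50 mM Na+, 25 nM strands)
  expect_equal(melting_temperature("ACGTACGTACGTACGTACGT", "nn"),
               53.0967, tolerance = 0.5 / 53)
  expect_warning(melting_temperature("ACGT", "nn"), "8 bp")
  # degenerate: average over expansions equals expanding by hand
  tm_y <- melting_temperature("ACGTACGTACGTACGTACYT", "nn")
  tm_exp <- mean(sapply(c("ACGTACGTACGTACGTACCT", "ACGTACGTACGTACGTACTT"),
                        melting_temperature, method = "nn"))
  expect_equal(tm_y, tm_exp)
})

test_that("reverse complement is IUPAC-aware and an involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAC"), "GTT")
  expect_equal(reverse_complement("AYG"), "CRT")
  expect_equal(reverse_complement("ASDN"), "NHST")
  set.seed(21)
  codes <- names(mbcprimer:::IUPAC_SETS)
  for (i in 1:50) {
    s <- paste(sample(codes, sample(5:30, 1), replace = TRUE), collapse = "")
    expect_equal(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("degenerate expansion is lexicographic, complete, and re-collapses", {
  expect_equal(expand_degenerate("AY"), c("AC", "AT"))
  expect_equal(expand_degenerate("AD"), c("AA", "AG", "AT"))
  expect_equal(expand_degenerate("ACGT"), "ACGT")
  expect_equal(degeneracy("NN"), 16)
  expect_equal(length(expand_degenerate("NYD")), 4 * 2 * 3)
  expect_error(expand_degenerate("NNNN", cap = 64), "exceeds cap")
  set.seed(33)
  codes <- names(mbcprimer:::IUPAC_SETS)
  for (i in 1:25) {
    s <- paste(sample(codes, 5, replace = TRUE), collapse = "")
    if (degeneracy(s) > 64) next
    ex <- expand_degenerate(s)
    expect_equal(length(ex), degeneracy(s))
    expect_false(any(duplicated(ex)))
    # re-collapsing expansions reproduces the minimal code per position
    mat <- do.call(rbind, strsplit(ex, ""))
    rebuilt <- paste(apply(mat, 2, function(col)
      mbcprimer:::iupac_collapse(col)), collapse = "")
    expect_equal(rebuilt, s)
  }
})

test_that("degenerate consensus proposal generalizes greedily and safely", {
  wv <- structure(list(start = 1, length = 4,
                       variants = list(target = c(ACGT = 9L, ATGT = 1L)),
                       covered = c(target = 10, exclusion = 0)),
                  class = "window_variants")
  rec <- suppressWarnings(propose_degenerate_consensus(wv, coverage_goal = 1))
  expect_equal(rec$sequence, "AYGT")
  expect_true(attr(rec, "goal_met"))
  expect_equal(attr(rec, "coverage"), 1)

  # single variant: unchanged
  wv$variants$target <- c(ACGT = 10L)
  expect_equal(suppressWarnings(propose_degenerate_consensus(wv, 1))$sequence, "ACGT")

  # goal already met by the plain candidate: no-op
  wv$variants$target <- c(ACGT = 9L, TTTT = 1L)
  expect_equal(suppressWarnings(propose_degenerate_consensus(wv, 0.9))$sequence, "ACGT")

  # coverage never decreases, fixed positions never altered
  wv$variants$target <- c(ACGT = 5L, ACGA = 3L, AGGT = 2L)
  rec2 <- suppressWarnings(propose_degenerate_consensus(wv, coverage_goal = 1))
  expect_gte(attr(rec2, "coverage"), 0.5)
  expect_equal(substr(rec2$sequence, 1, 1), "A")   # all variants agree at 1
  expect_true(attr(rec2, "goal_met"))

  # unreachable goal under a tight cap: best effort, flagged
  wv$variants$target <- c(ACGT = 4L, TGCA = 3L, CAGG = 3L)
  rec3 <- suppressWarnings(propose_degenerate_consensus(wv, coverage_goal = 1, cap = 2))
  expect_false(attr(rec3, "goal_met"))
  expect_lte(degeneracy(rec3$sequence), 2)
})

test_that("3'-end discrimination profiles the terminal positions", {
  r <- three_prime_mismatch_check("ACGTAAG", rep("ACGTAAT", 5))
  expect_equal(r$fractions[1], 1)
  expect_true(r$pass)
  # identical to the exclusion consensus: fail
  r2 <- three_prime_mismatch_check("ACGTAAG", rep("ACGTAAG", 5))
  expect_false(r2$pass)
  expect_equal(r2$fractions, c(0, 0, 0))
  # split terminal base: fraction 0.5 fails at the default 100%
  r3 <- three_prime_mismatch_check("ACGTAAG",
                                   c(rep("ACGTAAG", 2), rep("ACGTAAT", 2)))
  expect_equal(r3$fractions[1], 0.5)
  expect_false(r3$pass)
  expect_true(three_prime_mismatch_check("ACGTAAG",
                                         c(rep("ACGTAAG", 2), rep("ACGTAAT", 2)),
                                         min_fraction = 0.5)$pass)
  # IUPAC-aware: primer Y pairs with exclusion T -> not a mismatch
  r4 <- three_prime_mismatch_check("ACGTAAY", rep("ACGTAAT", 3))
  expect_false(r4$pass)
  # length-incompatible variants are refused, flagged
  r5 <- three_prime_mismatch_check("ACGTAAG", c("ACGTAAT", "ACG"))
  expect_equal(r5$n_refused, 1)
  expect_true(r5$pass)
  # abundance weighting
  r6 <- three_prime_mismatch_check("ACGTAAG", c("ACGTAAG", "ACGTAAT"),
                                   counts = c(1, 9))
  expect_equal(r6$fractions[1], 0.9)
})

test_that("approximate occurrence finds the minimum-mismatch hit on either strand", {
  ref <- paste0("TTTTTTTTTT", "ACGTTGCATGCAAGCTTGGC", "GGGGGGGGGG")
  hit <- approximate_occurrence("ACGTTGCATGCAAGCTTGGC", ref)
  expect_equal(hit$position, 11)
  expect_equal(hit$mismatches, 0)
  expect_equal(hit$strand, "forward")
  # degenerate position covers the reference base
  expect_equal(approximate_occurrence("AYG", "TTTATGTTT")$mismatches, 0)
  # reverse-complemented reference: same mismatch count, strand flagged
  rc <- reverse_complement(ref)
  hit_rc <- approximate_occurrence("ACGTTGCATGCAAGCTTGGC", rc)
  expect_equal(hit_rc$mismatches, 0)
  expect_equal(hit_rc$strand, "reverse")
  # mismatch counting
  ref1 <- paste0("TTTTTTTTTT", "ACGTTGCATGAAAGCTTGGC", "GGGGGGGGGG")
  expect_equal(approximate_occurrence("ACGTTGCATGCAAGCTTGGC", ref1)$mismatches, 1)
  # no hit beyond max_mm; short reference
  expect_null(approximate_occurrence("AAAAAAAAAA", "CCCCCCCCCCCCCC"))
  expect_null(approximate_occurrence("AAAAAAAAAA", "AAA"))
  # leftmost tie-break
  two <- paste0("ACGTACGTACGTACGTACGT", "TTTT", "ACGTACGTACGTACGTACGT")
  expect_equal(approximate_occurrence("ACGTACGTACGTACGTACGT", two)$position, 1)
})

test_that("coverage profiles are cumulative and strand-invariant", {
  primer <- "ACGTTGCATGCAAGCTTGGC"
  refs <- generate_reference_set(primer, c(rep(0, 8), 1, 3), seed = 19)
  covr <- coverage_profile(primer, refs)
  expect_equal(unname(covr$cov), c(0.8, 0.9, 0.9))
  expect_true(all(diff(covr$cov) >= 0))            # cumulative
  # reverse-complementing every reference changes nothing
  covr2 <- coverage_profile(primer, vapply(refs, reverse_complement, ""))
  expect_equal(covr$cov, covr2$cov)
  # present in all / absent beyond 2 mm everywhere
  refs0 <- generate_reference_set(primer, rep(0, 10), seed = 20)
  expect_equal(unname(coverage_profile(primer, refs0)$cov), c(1, 1, 1))
  refs4 <- generate_reference_set(primer, rep(6, 10), seed = 21)
  expect_equal(unname(coverage_profile(primer, refs4)$cov), c(0, 0, 0))
})

test_that("the four selection criteria use inclusive boundaries", {
  rec <- primer_record("p1", "ACGTTGCATGCAAGCTTGGC")   # GC 0.55, 20 bp
  covr <- structure(list(cov = c(mm0 = 0.7, mm1 = 0.83, mm2 = 0.9), n = 100),
                    class = "coverage_result")
  v <- apply_selection_criteria(rec, covr, three_prime_pass = TRUE)
  expect_true(v$pass)
  covr$cov[["mm1"]] <- 0.79
  expect_false(apply_selection_criteria(rec, covr, TRUE)$coverage)
  covr$cov[["mm1"]] <- 0.80                            # inclusive >=
  expect_true(apply_selection_criteria(rec, covr, TRUE)$coverage)
  # GC exactly 0.40 passes (inclusive)
  rec40 <- primer_record("p2", "ATATATATATATCGCGCGCG")
  expect_equal(rec40$gc_fraction, 0.4)
  expect_true(apply_selection_criteria(rec40, covr, TRUE)$gc)
  # length window 20 +/- 3
  rec17 <- primer_record("p3", "ACGTTGCATGCAAGCTT")
  expect_true(apply_selection_criteria(rec17, covr, TRUE)$length)
  rec16 <- primer_record("p4", "ACGTTGCATGCAAGCT")
  expect_false(apply_selection_criteria(rec16, covr, TRUE)$length)
  expect_false(apply_selection_criteria(rec, covr, FALSE)$pass)
})

test_that("pair compatibility screens Tm, geometry and 3' complementarity", {
  fw <- primer_record("fw", "ACGTTGCATGCAAGCTTGGC", "forward")
  rv <- primer_record("rv", reverse_complement("ACGTTGCATGCAAGCTTGGC"), "reverse")
  expect_equal(pair_compatibility(fw, rv, 1, 3500)$delta_tm, 0)
  expect_equal(pair_compatibility(fw, rv, 1, 3500)$predicted_amplicon_bp, 3500)
  expect_error(pair_compatibility(fw, rv, 100, 50), "downstream")

  # fw suffix ACGTT is reverse-complementary to AACGT inside rv: length-5
  # 3'-anchored run, failing the default (<5) threshold
  fw2 <- primer_record("fw2", "ATCATCATCATCATCACGTT", "forward")
  rv2 <- primer_record("rv2", "TCAAACGTATCATCATCATC", "reverse")
  pr <- pair_compatibility(fw2, rv2, 1, 1000)
  expect_equal(pr$three_prime_comp, 5)
  expect_false(pr$pass)
  # enumeration oracle: longest duplex over all substring pairs
  lcs_oracle <- function(a, b) {
    b <- reverse_complement(b)
    best <- 0
    for (i in seq_len(nchar(a))) for (j in i:nchar(a)) {
      if (grepl(substr(a, i, j), b, fixed = TRUE)) best <- max(best, j - i + 1)
    }
    best
  }
  set.seed(55)
  for (k in 1:20) {
    a <- random_dna(12); b <- random_dna(12)
    pa <- primer_record("a", a); pb <- primer_record("b", b)
    expect_equal(suppressWarnings(pair_compatibility(pa, pb, 1, 100))$heterodimer_score,
                 lcs_oracle(a, b))
  }
})
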