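test_that("polymorphism summary matches hand-computed cases", {
  # monomorphic
  aln <- cen_alignment(setNames(rep(strrep("A", 10), 4), paste0("s", 1:4)))
  ps <- polymorphism_summary(aln)
  expect_equal(ps$S, 0L)
  expect_equal(ps$pi, 0)
  expect_equal(ps$theta_w, 0)
  expect_equal(ps$n_sites_analysed, 10L)

  # 2 sequences, 1 difference in 10: pi = theta_w = 0.1 (a(2) = 1)
  ps2 <- polymorphism_summary(
    cen_alignment(c(a = "AAAAAAAAAA", b = "AAAAAAAAAT")))
  expect_equal(ps2$S, 1L)
  expect_equal(ps2$pi, 0.1)
  expect_equal(ps2$theta_w, 0.1)

  # (A,A,C,C) at one site of 10: per-site h = (4/3)(1 - 1/2) = 2/3
  ps3 <- polymorphism_summary(cen_alignment(
    c(a = "AAAAAAAAAA", b = "AAAAAAAAAA", c = "CAAAAAAAAA", d = "CAAAAAAAAA")))
  expect_equal(ps3$pi, (2 / 3) / 10)
  # cross-check: brute-force all-pairs 4/(6 pairs * 10 sites)
  expect_equal(ps3$pi, 4 / 60)
  expect_equal(ps3$theta_w, (1 / (1 + 1/2 + 1/3)) / 10)

  expect_error(polymorphism_summary(ps3 <- cen_alignment(c(a = "A", b = "A")),
                                    region = c(2, 2)), "region")
})

test_that("pi equals brute-force mean pairwise difference on random alignments with missing data", {
  set.seed(101)
  for (i in 1:200) {
    aln <- random_alignment(sample(2:8, 1), sample(2:50, 1))
    expect_equal(polymorphism_summary(aln)$pi, brute_pi(aln),
                 tolerance = 1e-12)
  }
})

test_that("pi and theta are invariant to strain/column permutation; all-N columns change nothing", {
  set.seed(5)
  for (i in 1:20) {
    aln <- random_alignment(6, 30)
    ps <- polymorphism_summary(aln)
    perm <- cen_alignment(aln$mat[sample(6), sample(30)], normalize = FALSE)
    psp <- polymorphism_summary(perm)
    expect_equal(ps$pi, psp$pi)
    expect_equal(ps$theta_w, psp$theta_w)
    expect_equal(ps$S, psp$S)
    padded <- cen_alignment(cbind(aln$mat,
                                  matrix("N", 6, 5)), normalize = FALSE)
    psn <- polymorphism_summary(padded)
    expect_equal(ps$pi, psn$pi)
    expect_equal(ps$theta_w, psn$theta_w)
    expect_equal(ps$n_sites_analysed, psn$n_sites_analysed)
  }
})

test_that("Dxy matches hand cases and brute-force pair enumeration", {
  pops <- c(a = "P1", b = "P1", c = "P2", d = "P2")
  aln <- cen_alignment(c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA"))
  expect_equal(pairwise_divergence_dxy(aln, pops, "P1", "P2")$dxy, 0)

  aln2 <- cen_alignment(c(a = "AAAA", c = "AAAT"))
  expect_equal(pairwise_divergence_dxy(aln2, pops, "P1", "P2")$dxy, 0.25)

  set.seed(33)
  for (i in 1:50) {
    aln <- random_alignment(4, sample(4:30, 1))
    rownames(aln$mat) <- names(pops)
    aln$strains <- names(pops)
    d <- pairwise_divergence_dxy(aln, pops, "P1", "P2")$dxy
    expect_equal(d, brute_dxy(aln, pops, "P1", "P2"), tolerance = 1e-12)
  }
  expect_error(pairwise_divergence_dxy(aln2, pops, "P1", "P9"), "absent")
})

test_that("locus bootstrap is deterministic under seed and degenerate on constant input", {
  const <- bootstrap_ci(rep(3.5, 5), "mean", n_reps = 100, seed = 1)
  expect_equal(const$point, 3.5)
  expect_equal(const$ci_low, 3.5)
  expect_equal(const$ci_high, 3.5)

  b1 <- bootstrap_ci(c(0, 1), "mean", n_reps = 10, seed = 9)
  b2 <- bootstrap_ci(c(0, 1), "mean", n_reps = 10, seed = 9)
  expect_identical(b1, b2)
  expect_error(bootstrap_ci(1, "mean"), "degenerate")

  # agreement with an independent resampler under the same seed protocol
  vals <- runif(16)
  b <- bootstrap_ci(vals, "mean", n_reps = 10000, seed = 4)
  reps <- withr::with_seed(4, vapply(1:10000, function(i) {
    mean(vals[sample.int(16, 16, replace = TRUE)])
  }, numeric(1)))
  expect_equal(unname(c(b$ci_low, b$ci_high)),
               unname(quantile(reps, c(0.025, 0.975))))
})

test_that("homopolymer runs are maximal, broken by N/gaps, with 4-mer counts exposed", {
  hp <- homopolymer_runs("AAAAA", min_len = 5)
  expect_equal(hp$runs$start, 1L)
  expect_equal(hp$runs$end, 5L)

  expect_equal(homopolymer_runs("AAAANAAAA", min_len = 5)$n_runs, 0L)
  expect_equal(homopolymer_runs("AAAA-AAAA", min_len = 5)$n_runs, 0L)

  hp3 <- homopolymer_runs("TTTTCCCCCAA", min_len = 4)
  expect_equal(hp3$runs$base, c("T", "C"))
  expect_equal(hp3$runs$start, c(1L, 5L))
  expect_equal(hp3$runs$end, c(4L, 9L))

  expect_equal(homopolymer_runs("AAAAGTTTT", min_len = 5)$n_len4, 2L)
})

test_that("exact binomial p-values agree with full enumeration at small n", {
  expect_equal(binomial_exact_test(3, 3, 0.5), 0.25)
  set.seed(8)
  for (i in 1:50) {
    n <- sample(1:12, 1)
    x <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    expect_equal(binomial_exact_test(x, n, p0), enum_binom_p(x, n, p0),
                 tolerance = 1e-9)
  }
  expect_error(binomial_exact_test(5, 3, 0.5), "input error")
  expect_error(binomial_exact_test(1, 3, 1.2), "input error")
})
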