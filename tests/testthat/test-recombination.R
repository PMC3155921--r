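test_that("four-gamete test finds incompatibilities only when all four gametes are jointly valid", {
  # <= 3 sequences can show at most 3 gametes
  aln3 <- cen_alignment(c(a = "AA", b = "AT", c = "TA"))
  expect_equal(nrow(incompatible_pairs(aln3)), 0L)

  aln4 <- cen_alignment(c(a = "AA", b = "AT", c = "TA", d = "TT"))
  ip <- incompatible_pairs(aln4)
  expect_equal(nrow(ip), 1L)
  expect_equal(c(ip$site_a, ip$site_b), c(1L, 2L))
  expect_equal(unlist(ip[, c("n00", "n01", "n10", "n11")]),
               c(n00 = 1L, n01 = 1L, n10 = 1L, n11 = 1L))

  # masking one gamete carrier removes the signal
  alnN <- cen_alignment(c(a = "AA", b = "AT", c = "TA", d = "TN"))
  expect_equal(nrow(incompatible_pairs(alnN)), 0L)

  # sites with 3+ valid bases are excluded but logged
  alnM <- cen_alignment(c(a = "AA", b = "CT", c = "GA", d = "AT"))
  ipM <- incompatible_pairs(alnM)
  expect_equal(attr(ipM, "multiallelic_sites"), 1L)
})

test_that("Hudson-Kaplan bound equals brute force on small interval sets", {
  expect_equal(hudson_kaplan_rmin(data.frame(site_a = integer(0),
                                             site_b = integer(0))), 0L)
  expect_equal(hudson_kaplan_rmin(data.frame(site_a = c(1, 2),
                                             site_b = c(5, 6))), 1L)
  expect_equal(hudson_kaplan_rmin(data.frame(site_a = c(1, 4),
                                             site_b = c(3, 8))), 2L)
  set.seed(17)
  for (i in 1:200) {
    m <- sample(1:8, 1)
    a <- sample(1:20, m, replace = TRUE)
    b <- a + sample(2:10, m, replace = TRUE)
    expect_equal(hudson_kaplan_rmin(data.frame(site_a = a, site_b = b)),
                 brute_rmin(a, b))
  }
})

test_that("minimum homoplasy set is an exact, lexicographically smallest vertex cover", {
  # no incompatibilities
  mono <- cen_alignment(setNames(rep("AAAA", 4), paste0("s", 1:4)))
  mhs <- min_homoplasy_set(mono)
  expect_equal(mhs$k_obs, 0L)
  expect_equal(mhs$sites, integer(0))

  # single incompatible pair: tie broken toward the smaller site index
  aln4 <- cen_alignment(c(a = "AA", b = "AT", c = "TA", d = "TT"))
  mhs2 <- min_homoplasy_set(aln4)
  expect_equal(mhs2$k_obs, 1L)
  expect_equal(mhs2$sites, 1L)

  # star graphs: the hub alone covers everything
  set.seed(23)
  for (i in 1:100) {
    nv <- sample(4:12, 1)
    edges <- t(combn(nv, 2))
    edges <- edges[sample(nrow(edges), sample(3:min(12, nrow(edges)), 1)), ,
                   drop = FALSE]
    k_bb <- pointcen:::.min_cover_size(edges)
    expect_equal(k_bb, exhaustive_min_cover_size(edges))
    cover <- sort(pointcen:::.lex_min_cover(edges, k_bb))
    expect_equal(length(cover), k_bb)
    # every edge covered
    expect_true(all(edges[, 1] %in% cover | edges[, 2] %in% cover))
  }
})

test_that("removing the inferred set clears incompatibilities; unrelated removals change nothing", {
  set.seed(61)
  sim <- simulate_coalescent_alignment(n_strains = 16, length = 200,
                                       theta = 0.04, n_crossovers = 1,
                                       seed = 77)
  aln <- sim$alignment
  mhs <- min_homoplasy_set(aln)
  if (mhs$k_obs > 0) {
    after <- retest_after_removal(aln, mhs$sites)
    expect_equal(nrow(after), 0L)
    # rmin = 0 iff no pairs iff k_obs = 0 (linked-invariants check)
    expect_gt(hudson_kaplan_rmin(mhs$pairs), 0L)
  }
  before <- incompatible_pairs(aln)
  unrelated <- setdiff(seq_len(aln_length(aln)),
                       unique(c(before$site_a, before$site_b)))[1:3]
  again <- retest_after_removal(aln, unrelated)
  expect_equal(nrow(again), nrow(before))

  # flank incompatibilities survive removal of a core-only cover: columns
  # 1-2 conflict (core), columns 5-6 conflict (flank), column 2 is
  # four-gamete-compatible with both flank columns by construction
  two <- cen_alignment(c(s1 = "ATAAGCCC", s2 = "ATAAGGCC", s3 = "TTAACGCC",
                         s4 = "TAAACCCC", s5 = "AAAACCCC", s6 = "AAAACCCC"))
  core_cover <- min_homoplasy_set(two, region = c(1, 4))
  expect_equal(core_cover$k_obs, 1L)
  expect_equal(core_cover$sites, 1L)
  left <- retest_after_removal(two, core_cover$sites)
  expect_equal(nrow(left), 1L)
  expect_equal(c(left$site_a, left$site_b), c(5L, 6L))
})

test_that("homoplasy null p-value matches the exact occupancy chain at L=2, S=2 and is deterministic", {
  # exact: first site repeats before the second distinct site is hit with
  # probability 1/2, so P(homoplasious count >= 1) = 1/2
  res <- homoplasy_null_pvalue(2, 2, 1, n_reps = 10000, seed = 12)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(res$p_value - 0.5), 4 * se + 2 / 10001)

  expect_equal(homoplasy_null_pvalue(50, 10, 0, n_reps = 37, seed = 1)$p_value, 1)
  r1 <- homoplasy_null_pvalue(100, 20, 2, n_reps = 500, seed = 3)
  r2 <- homoplasy_null_pvalue(100, 20, 2, n_reps = 500, seed = 3)
  expect_identical(r1$p_value, r2$p_value)
  expect_error(homoplasy_null_pvalue(5, 10, 1), "S > L")

  # the "total" conditioning variant is exposed and differs in distribution
  rt <- homoplasy_null_pvalue(10, 8, 1, n_reps = 2000, seed = 5,
                              model = "total")
  expect_true(rt$p_value > 0 && rt$p_value <= 1)
})

test_that("full homoplasy analysis ties the pieces together consistently", {
  sim <- simulate_coalescent_alignment(n_strains = 20, length = 150,
                                       theta = 0.06, seed = 9)
  res <- homoplasy_analysis(sim$alignment, n_reps = 199, seed = 2)
  expect_s3_class(res, "homoplasy_result")
  expect_equal(res$rmin == 0L, nrow(res$incompatible_pairs) == 0L)
  expect_equal(res$k_obs == 0L, nrow(res$incompatible_pairs) == 0L)
  expect_gte(res$p_value, 0)
  expect_lte(res$p_value, 1)
  after <- retest_after_removal(sim$alignment, res$min_homoplasy_set)
  expect_equal(nrow(after), 0L)
})
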