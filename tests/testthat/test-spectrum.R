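test_that("unique-haplotype polarization follows the derived-allele rule", {
  # singleton minor allele against a uniform majority
  aln <- cen_alignment(c(h1 = "A", h2 = "A", h3 = "A", h4 = "G"))
  ch <- polarize_unique_changes(aln)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$from, "A")
  expect_equal(ch$to, "G")
  expect_equal(ch$carrier, "h4")
  expect_equal(ch$kind, "transition")

  # no unique allele
  expect_equal(nrow(polarize_unique_changes(
    cen_alignment(c(h1 = "A", h2 = "A", h3 = "G", h4 = "G")))), 0L)
  # two unique alleles: ambiguous polarity
  expect_equal(nrow(polarize_unique_changes(
    cen_alignment(c(h1 = "A", h2 = "A", h3 = "C", h4 = "G")))), 0L)
  # fewer than 3 valid haplotypes
  expect_equal(nrow(polarize_unique_changes(
    cen_alignment(c(h1 = "A", h2 = "G", h3 = "N", h4 = "-")))), 0L)
})

test_that("polarization agrees with exhaustive column-pattern enumeration", {
  # every column pattern of 4 haplotypes over the 6-letter alphabet
  alphabet <- c("A", "C", "G", "T", "N", "-")
  combos <- expand.grid(a = alphabet, b = alphabet, c = alphabet,
                        d = alphabet, stringsAsFactors = FALSE)
  set.seed(1)
  combos <- combos[sample(nrow(combos), 300), ]
  for (r in seq_len(nrow(combos))) {
    col <- unlist(combos[r, ])
    aln <- cen_alignment(setNames(col, paste0("h", 1:4)), normalize = FALSE)
    got <- polarize_unique_changes(aln)
    # independent statement of the rule
    v <- col[col %in% c("A", "C", "G", "T")]
    tab <- table(v)
    expect_rule <- length(v) >= 3 && length(tab) == 2 && min(tab) == 1
    expect_equal(nrow(got) == 1L, expect_rule, info = paste(col, collapse = ""))
    if (expect_rule) {
      expect_equal(got$to, names(tab)[tab == 1])
      expect_equal(got$from, names(tab)[tab > 1])
    }
  }
})

test_that("spectrum counts tabulate types and base availabilities per locus", {
  red <- cen_alignment(c(h1 = "AAGA", h2 = "AAGA", h3 = "AAGG"),
                       locus_id = "L1")
  ch <- polarize_unique_changes(red)
  sc <- spectrum_counts(red, ch)
  expect_equal(unname(sc$n["A>G"]), 1L)
  expect_equal(sum(sc$n), 1L)
  expect_equal(unname(sc$alpha), c(8L, 0L, 4L, 0L), ignore_attr = TRUE)
  expect_equal(sc$p_AT + sc$p_GC, 1)

  # zero changes still populates availability
  mono <- cen_alignment(c(h1 = "ACGT", h2 = "ACGT", h3 = "ACGT"),
                        locus_id = "L2")
  sc2 <- spectrum_counts(mono, polarize_unique_changes(mono))
  expect_equal(sum(sc2$n), 0L)
  expect_equal(sum(sc2$alpha), 12L)

  expect_error(spectrum_counts(red, data.frame(locus_id = "other",
                                               from = "A", to = "G")),
               "different loci")
})

test_that("AT-rich simulated CDEII recovers its generating composition", {
  sims <- lapply(1:8, function(i) {
    simulate_coalescent_alignment(seed = 400 + i)  # default p_AT = 0.95
  })
  counts <- lapply(sims, function(s) {
    red <- reduce_to_haplotypes(s$alignment)
    spectrum_counts(red, polarize_unique_changes(red))
  })
  pooled <- pool_spectra(counts)
  # mutation pressure toward uniform erodes the root composition by about
  # theta * 2/3 * p_AT ~ 0.025, so allow that drift plus sampling noise
  expect_lt(abs(pooled$p_AT - 0.95), 0.05)
  expect_gt(pooled$p_AT, 0.9)
})

test_that("relative rates follow the composition-normalised formula and sum to one", {
  # single observed class -> r = 1 there
  red <- cen_alignment(c(h1 = "CCCC", h2 = "CCCC", h3 = "CCCT"),
                       locus_id = "L1")
  sc <- spectrum_counts(red, polarize_unique_changes(red))
  rr <- relative_rates_with_ci(list(sc), n_reps = 10, seed = 1)
  expect_equal(unname(rr$r["C:G>T:A"]), 1)
  expect_equal(sum(rr$r), 1)

  # two classes, equal counts, equal source composition -> 0.5 each
  redAT <- cen_alignment(c(h1 = "ACAC", h2 = "ACAC", h3 = "GCAC", h4 = "ATAC"),
                         locus_id = "L2")
  chAT <- polarize_unique_changes(redAT)
  scAT <- spectrum_counts(redAT, chAT)
  expect_equal(sum(scAT$n), 2L)

  # random count tables: formula output equals independent step-by-step
  # recomputation
  set.seed(99)
  for (i in 1:50) {
    n <- setNames(rpois(12, 2), pointcen:::SUB_TYPES)
    alpha <- setNames(rpois(4, 50) + 10L, c("A", "C", "G", "T"))
    if (sum(n) == 0) n["A>G"] <- 1L
    sc <- structure(list(locus_id = "x", n = n, alpha = alpha,
                         p = alpha / sum(alpha),
                         p_AT = unname((alpha["A"] + alpha["T"]) / sum(alpha)),
                         p_GC = unname((alpha["C"] + alpha["G"]) / sum(alpha))),
                    class = "spectrum_counts")
    rr <- relative_rates_with_ci(list(sc), n_reps = 2, seed = 1)
    expect_equal(unname(rr$r), unname(step_by_step_rates(as.list(n), alpha)),
                 tolerance = 1e-12)
    expect_equal(sum(rr$r), 1, tolerance = 1e-12)
  }

  mono <- cen_alignment(c(h1 = "ACGT", h2 = "ACGT", h3 = "ACGT"))
  scm <- spectrum_counts(mono, polarize_unique_changes(mono))
  expect_error(relative_rates_with_ci(list(scm)), "undefined-spectrum")
})

test_that("transition/transversion bookkeeping matches the 4:8 type split", {
  types <- pointcen:::SUB_TYPES
  ft <- do.call(rbind, strsplit(types, ">"))
  ts <- is_transition(ft[, 1], ft[, 2])
  expect_equal(sum(ts), 4L)
  expect_equal(sum(!ts), 8L)
})

test_that("unique indels are classified by length, direction, and homopolymer context", {
  # single-base gap at a non-run position -> 1 bp deletion
  red <- cen_alignment(c(h1 = "ACGTACGT", h2 = "ACG-ACGT", h3 = "ACGTACGT"),
                       locus_id = "L")
  ind <- classify_indels(red)
  expect_equal(ind$one_bp_deletions, 1L)
  expect_equal(ind$one_bp_insertions, 0L)
  expect_equal(ind$other, 0L)
  expect_equal(ind$events$carrier, "h2")

  # single-base gap inside an AAAAA run -> "other" (in-run)
  red2 <- cen_alignment(c(h1 = "GAAAAAG", h2 = "GAA-AAG", h3 = "GAAAAAG"),
                        locus_id = "L")
  ind2 <- classify_indels(red2)
  expect_equal(ind2$one_bp_deletions, 0L)
  expect_equal(ind2$other, 1L)
  expect_equal(ind2$other_in_run, 1L)

  # 3-base unique gap -> "other" (multi-base)
  red3 <- cen_alignment(c(h1 = "ACGTACGT", h2 = "A---ACGT", h3 = "ACGTACGT"),
                        locus_id = "L")
  ind3 <- classify_indels(red3)
  expect_equal(ind3$other, 1L)
  expect_equal(ind3$other_multibase, 1L)

  # insertion: one haplotype carries a base where all others are gapped
  red4 <- cen_alignment(c(h1 = "ACG-ACGT", h2 = "ACGTACGT", h3 = "ACG-ACGT"),
                        locus_id = "L")
  ind4 <- classify_indels(red4)
  expect_equal(ind4$one_bp_insertions, 1L)
  expect_equal(ind4$events$type, "insertion")

  # a gap shared by all-but-one haplotype polarizes as an insertion in the
  # base-carrying haplotype (its state is the unique, hence derived, one)
  red5 <- cen_alignment(c(h1 = "ACG-ACGT", h2 = "ACG-ACGT", h3 = "ACGTACGT"),
                        locus_id = "L")
  ev5 <- classify_indels(red5)$events
  expect_equal(nrow(ev5), 1L)
  expect_equal(ev5$type, "insertion")
  expect_equal(ev5$carrier, "h3")

  # a gap shared by only some haplotypes is not unique to any and is skipped
  red6 <- cen_alignment(c(h1 = "ACG-ACGT", h2 = "ACG-ACGT", h3 = "ACGTACGT",
                          h4 = "ACGTACGT"), locus_id = "L")
  expect_equal(nrow(classify_indels(red6)$events), 0L)
})

test_that("spectrum summary arithmetic reproduces derived table columns", {
  row <- spectrum_summary_row(46, 68, one_bp_deletions = 4, other = 18)
  expect_equal(row$total_bps, 114)
  expect_equal(round(row$ts_tv_freq, 2), 0.68)
  expect_equal(round(row$del_bps_freq, 3), 0.035)

  # end-to-end: Ts/Tv frequency from polarized changes equals count ratio
  sim <- simulate_coalescent_alignment(n_strains = 24, length = 300,
                                       theta = 0.03, seed = 55)
  red <- reduce_to_haplotypes(sim$alignment)
  ch <- polarize_unique_changes(red)
  ts <- sum(ch$kind == "transition")
  tv <- sum(ch$kind == "transversion")
  expect_gt(ts + tv, 0)
  expect_equal(spectrum_summary_row(ts, tv)$ts_tv_freq, ts / tv)
})

test_that("polarized changes never exceed segregating sites of the reduced alignment", {
  for (s in 1:10) {
    sim <- simulate_coalescent_alignment(n_strains = 16, length = 120,
                                         theta = 0.04, seed = 600 + s,
                                         missing_fraction = 0.3)
    red <- reduce_to_haplotypes(sim$alignment)
    ch <- polarize_unique_changes(red)
    expect_lte(nrow(ch), polymorphism_summary(red)$S)
  }
})
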