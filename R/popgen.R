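# Harmonic number a(n) = sum_{k=1}^{n-1} 1/k, the Watterson correction.
.watterson_a <- function(n) {
  vapply(n, function(m) if (m < 2L) NA_real_ else sum(1 / seq_len(m - 1L)),
         numeric(1))
}

# Per-column base counts for an alignment matrix: 4 x L integer matrix.
.base_counts <- function(mat, region = NULL) {
  if (!is.null(region)) {
    stopifnot(length(region) == 2L)
    if (region[1] < 1L || region[2] > ncol(mat) || region[1] > region[2]) {
      stop("input error: region outside alignment")
    }
    mat <- mat[, region[1]:region[2], drop = FALSE]
  }
  counts <- vapply(BASES, function(b) colSums(mat == b),
                   numeric(ncol(mat)))
  if (ncol(mat) == 1L) counts <- matrix(counts, nrow = 1L,
                                        dimnames = list(NULL, BASES))
  t(counts)  # 4 x L
}

#' Missing-data-aware polymorphism summary for one region
#'
#' Statistics are computed from every column with at least two valid bases
#' (`A C G T`; `N` and `-` are missing data), matching pairwise-deletion
#' handling of low-coverage alignments. Per column with local sample size
#' n >= 2, heterozygosity uses the unbiased form
#' `h = n/(n-1) * (1 - sum p_b^2)` and the per-site Watterson contribution is
#' `s / a(n)` with `a(n) = sum_{k<n} 1/k` and `s` the 0/1 segregation
#' indicator. Both are averaged over the analysed (not total) columns.
#'
#' @param aln A `cen_alignment`.
#' @param region `NULL` (whole alignment) or `c(start, end)`, 1-based
#'   inclusive.
#' @return List of class `polymorphism_summary`: `locus_id`, `region`,
#'   `n_sites_analysed`, `S`, `pi`, `theta_w`.
#' @export
polymorphism_summary <- function(aln, region = NULL) {
  counts <- .base_counts(aln$mat, region)
  n <- colSums(counts)
  analysed <- n >= 2L
  n_sites <- sum(analysed)
  if (ncol(counts) == 0L) stop("input error: empty region")
  if (n_sites == 0L) {
    out <- list(locus_id = aln$locus_id, region = region,
                n_sites_analysed = 0L, S = 0L, pi = 0, theta_w = 0)
    class(out) <- "polymorphism_summary"
    return(out)
  }
  distinct <- colSums(counts > 0L)
  seg <- analysed & distinct >= 2L
  S <- sum(seg)
  # unbiased per-site heterozygosity at local sample size n
  sumsq <- colSums(counts^2)
  h <- ifelse(analysed, (n / (n - 1)) * (1 - sumsq / n^2), 0)
  pi <- sum(h[analysed]) / n_sites
  a_n <- .watterson_a(n)
  theta_w <- sum(1 / a_n[seg]) / n_sites
  if (S == 0L) theta_w <- 0
  out <- list(locus_id = aln$locus_id, region = region,
              n_sites_analysed = as.integer(n_sites), S = as.integer(S),
              pi = pi, theta_w = theta_w)
  class(out) <- "polymorphism_summary"
  out
}

#' @export
print.polymorphism_summary <- function(x, ...) {
  reg <- if (is.null(x$region)) "whole" else paste(x$region, collapse = "-")
  cat(sprintf(
    "%s [%s]: %d sites analysed, S = %d, pi = %.4g, theta_w = %.4g\n",
    x$locus_id, reg, x$n_sites_analysed, x$S, x$pi, x$theta_w
  ))
  invisible(x)
}

#' Mean between-population divergence (Dxy)
#'
#' Raw (not net) divergence: at each column with at least one valid base in
#' each population, the proportion of differing cross-population base pairs
#' is computed, and Dxy is the mean of that proportion over the analysed
#' columns.
#'
#' @param aln A `cen_alignment`.
#' @param pops Named character vector strain -> population
#'   ([read_population_map()]).
#' @param pop_a,pop_b Population labels.
#' @param region Optional `c(start, end)`.
#' @return List of class `divergence_summary`: `locus_id`, `pop_a`, `pop_b`,
#'   `dxy`, `n_sites_analysed`.
#' @export
pairwise_divergence_dxy <- function(aln, pops, pop_a, pop_b, region = NULL) {
  strains_a <- aln$strains[aln$strains %in% names(pops)[pops == pop_a]]
  strains_b <- aln$strains[aln$strains %in% names(pops)[pops == pop_b]]
  if (length(strains_a) == 0L || length(strains_b) == 0L) {
    stop(sprintf("input error: population '%s' absent from alignment",
                 if (length(strains_a) == 0L) pop_a else pop_b))
  }
  ca <- .base_counts(aln$mat[strains_a, , drop = FALSE], region)
  cb <- .base_counts(aln$mat[strains_b, , drop = FALSE], region)
  na <- colSums(ca)
  nb <- colSums(cb)
  analysed <- na >= 1L & nb >= 1L
  if (!any(analysed)) {
    d <- NA_real_
  } else {
    matches <- colSums(ca * cb)
    d_site <- 1 - matches[analysed] / (na[analysed] * nb[analysed])
    d <- mean(d_site)
  }
  out <- list(locus_id = aln$locus_id, pop_a = pop_a, pop_b = pop_b,
              dxy = d, n_sites_analysed = as.integer(sum(analysed)))
  class(out) <- "divergence_summary"
  out
}

#' Bootstrap confidence interval over a set of loci
#'
#' Resamples loci with replacement and reports percentile 2.5/97.5 bounds;
#' bit-reproducible under a fixed seed.
#'
#' @param values Numeric vector of per-locus statistics (length >= 2).
#' @param statistic `"mean"` or `"median"`.
#' @param n_reps Number of bootstrap replicates (default 10000).
#' @param seed Integer RNG seed.
#' @return List of class `locus_set_estimate`: `statistic`, `point`,
#'   `ci_low`, `ci_high`, `n_loci`, `n_reps`, `seed`.
#' @export
bootstrap_ci <- function(values, statistic = c("mean", "median"),
                         n_reps = 10000L, seed = 1L) {
  statistic <- match.arg(statistic)
  if (length(values) < 2L) {
    stop("degenerate-input error: need >= 2 loci for a bootstrap CI")
  }
  stopifnot(n_reps >= 1L)
  fn <- if (statistic == "mean") mean else median
  n <- length(values)
  reps <- withr::with_seed(seed, {
    vapply(seq_len(n_reps),
           function(i) fn(values[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  ci <- unname(quantile(reps, c(0.025, 0.975), type = 7))
  out <- list(statistic = statistic, point = fn(values),
              ci_low = ci[1], ci_high = ci[2],
              n_loci = n, n_reps = as.integer(n_reps), seed = as.integer(seed))
  class(out) <- "locus_set_estimate"
  out
}

#' @export
print.locus_set_estimate <- function(x, ...) {
  cat(sprintf("%s = %.4g (95%% CI %.4g-%.4g; %d loci, %d bootstrap reps)\n",
              x$statistic, x$point, x$ci_low, x$ci_high, x$n_loci, x$n_reps))
  invisible(x)
}

#' Maximal homopolymer runs in a sequence
#'
#' A run is a maximal stretch of one repeated valid base; `N` or `-` breaks a
#' run. Runs at least `min_len` long are reported; the count of exact
#' length-4 runs is also exposed, since 4 bp runs remain after excluding
#' longer ones and still attract slippage.
#'
#' @param seq Character string (or character vector of single characters)
#'   over `A C G T N -`.
#' @param min_len Minimum reported run length (default 5).
#' @return List of class `homopolymer_profile`: `runs` (data.frame base,
#'   start, end, length for runs >= min_len), `counts_by_length` (table over
#'   all maximal run lengths >= 2), `n_runs`, `n_len4`, `seq_length`.
#' @export
homopolymer_runs <- function(seq, min_len = 5L) {
  chars <- if (length(seq) == 1L) strsplit(seq, "", fixed = TRUE)[[1]] else seq
  chars <- toupper(chars)
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep_base <- r$values %in% BASES
  runs_all <- data.frame(base = r$values[keep_base],
                         start = starts[keep_base], end = ends[keep_base],
                         length = r$lengths[keep_base],
                         stringsAsFactors = FALSE)
  ge2 <- runs_all[runs_all$length >= 2L, , drop = FALSE]
  keep <- runs_all[runs_all$length >= min_len, , drop = FALSE]
  rownames(keep) <- NULL
  out <- list(
    runs = keep,
    counts_by_length = table(ge2$length),
    n_runs = nrow(keep),
    n_len4 = sum(runs_all$length == 4L),
    seq_length = length(chars)
  )
  class(out) <- "homopolymer_profile"
  out
}

#' Exact two-sided binomial test (minimum-likelihood method)
#'
#' Two-sided p-value obtained by summing the probabilities of all outcomes
#' whose point probability does not exceed that of the observed outcome —
#' the convention implemented by [stats::binom.test()], which this wraps.
#'
#' @param x Successes (0..n).
#' @param n Trials.
#' @param p0 Null success probability (0 < p0 < 1).
#' @return The two-sided p-value.
#' @export
binomial_exact_test <- function(x, n, p0) {
  if (n < 0L || x < 0L || x > n) stop("input error: need 0 <= x <= n")
  if (p0 <= 0 || p0 >= 1) stop("input error: need 0 < p0 < 1")
  unname(binom.test(x, n, p = p0, alternative = "two.sided")$p.value)
}
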