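# Binary allele coding for biallelic columns: for each column with exactly
# two distinct valid bases, code the alphabetically first base 0, second 1,
# NA where the strain has N or a gap. Columns with 3+ valid bases are
# excluded from pair testing (each is direct homoplasy evidence, logged via
# the "multiallelic_sites" attribute); sites with >2 states cannot enter the
# two-locus four-gamete frame.
.biallelic_coding <- function(mat, region = NULL) {
  offset <- 0L
  if (!is.null(region)) {
    stopifnot(length(region) == 2L)
    if (region[1] < 1L || region[2] > ncol(mat) || region[1] > region[2]) {
      stop("input error: region outside alignment")
    }
    offset <- region[1] - 1L
    mat <- mat[, region[1]:region[2], drop = FALSE]
  }
  counts <- .base_counts(mat)
  distinct <- colSums(counts > 0L)
  bi <- which(distinct == 2L)
  multi <- which(distinct >= 3L)
  coding <- matrix(NA_integer_, nrow = nrow(mat), ncol = length(bi))
  alleles <- matrix(NA_character_, nrow = 2L, ncol = length(bi))
  for (k in seq_along(bi)) {
    col <- mat[, bi[k]]
    ab <- BASES[counts[, bi[k]] > 0L]
    alleles[, k] <- ab
    coding[col == ab[1], k] <- 0L
    coding[col == ab[2], k] <- 1L
  }
  list(coding = coding, sites = bi + offset, alleles = alleles,
       multiallelic = multi + offset)
}

#' Four-gamete test over all biallelic site pairs
#'
#' Two biallelic sites are incompatible when, among the strains with a valid
#' base at both, all four two-site haplotypes occur — evidence of either a
#' recombination event between them or repeat mutation (homoplasy) at one of
#' them. Gaps and `N` are excluded per strain per site.
#'
#' @param aln A `cen_alignment`.
#' @param region `NULL` or `c(start, end)` 1-based inclusive. Reported site
#'   indices are always in full-alignment coordinates.
#' @return data.frame of class `incompatible_pairs`: `site_a`, `site_b`
#'   (site_a < site_b), allele labels, and the four gamete counts `n00 n01
#'   n10 n11`. Attributes: `biallelic_sites`, `multiallelic_sites`.
#' @export
incompatible_pairs <- function(aln, region = NULL) {
  bc <- .biallelic_coding(aln$mat, region)
  m <- ncol(bc$coding)
  rows <- list()
  if (m >= 2L && nrow(bc$coding) >= 4L) {
    for (i in seq_len(m - 1L)) {
      xi <- bc$coding[, i]
      for (j in (i + 1L):m) {
        xj <- bc$coding[, j]
        ok <- !is.na(xi) & !is.na(xj)
        if (sum(ok) < 4L) next
        g <- xi[ok] * 2L + xj[ok]
        tab <- tabulate(g + 1L, nbins = 4L)
        if (all(tab > 0L)) {
          rows[[length(rows) + 1L]] <- data.frame(
            site_a = bc$sites[i], site_b = bc$sites[j],
            alleles_a = paste(bc$alleles[, i], collapse = "/"),
            alleles_b = paste(bc$alleles[, j], collapse = "/"),
            n00 = tab[1], n01 = tab[2], n10 = tab[3], n11 = tab[4],
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    site_a = integer(0), site_b = integer(0),
    alleles_a = character(0), alleles_b = character(0),
    n00 = integer(0), n01 = integer(0), n10 = integer(0), n11 = integer(0),
    stringsAsFactors = FALSE
  )
  attr(out, "biallelic_sites") <- bc$sites
  attr(out, "multiallelic_sites") <- bc$multiallelic
  class(out) <- c("incompatible_pairs", "data.frame")
  out
}

#' Hudson-Kaplan lower bound on the number of recombination events
#'
#' Each incompatible pair requires at least one event in the open interval
#' between its two sites; the classic interval-removal bound is the minimum
#' number of points stabbing all such intervals, found greedily after
#' sorting by right endpoint.
#'
#' @param pairs data.frame with columns `site_a`, `site_b`
#'   ([incompatible_pairs()] output).
#' @return Integer R_min >= 0.
#' @export
hudson_kaplan_rmin <- function(pairs) {
  if (nrow(pairs) == 0L) return(0L)
  a <- pairs$site_a
  b <- pairs$site_b
  ord <- order(b, a)
  count <- 0L
  cur <- -Inf
  for (k in ord) {
    if (a[k] >= cur) {  # open interval (a,b): an event placed just left of
      count <- count + 1L  # cur = b covers every interval with a < b
      cur <- b[k]
    }
  }
  count
}

# --- exact minimum vertex cover (branch and bound) ---------------------------

# edges: 2-column integer matrix of vertex indices (local 1..n numbering)
.min_cover_size <- function(edges, best = Inf) {
  if (nrow(edges) == 0L) return(0L)
  if (best <= 0L) return(Inf)
  deg <- table(c(edges[, 1], edges[, 2]))
  v <- as.integer(names(deg)[which.max(deg)])
  # branch 1: include v
  e1 <- edges[edges[, 1] != v & edges[, 2] != v, , drop = FALSE]
  s1 <- 1L + .min_cover_size(e1, best - 1L)
  best <- min(best, s1)
  # branch 2: exclude v -> include all neighbours of v
  nb <- unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
  if (length(nb) < best) {
    keep <- !(edges[, 1] %in% c(v, nb)) & !(edges[, 2] %in% c(v, nb))
    s2 <- length(nb) + .min_cover_size(edges[keep, , drop = FALSE],
                                       best - length(nb))
    best <- min(best, s2)
  }
  best
}

# Lexicographically smallest minimum cover of size k (vertices are global
# site indices; smallest index first). Correctness: v belongs to some
# minimum cover iff removing it leaves a graph coverable with k-1 vertices.
.lex_min_cover <- function(edges, k) {
  if (nrow(edges) == 0L) return(integer(0))
  verts <- sort(unique(c(edges[, 1], edges[, 2])))
  for (v in verts) {
    rest <- edges[edges[, 1] != v & edges[, 2] != v, , drop = FALSE]
    if (.min_cover_size(rest, k) <= k - 1L) {
      return(c(v, .lex_min_cover(rest, k - 1L)))
    }
  }
  stop("internal error: no cover of size k found")  # unreachable for valid k
}

#' Minimum set of homoplasious sites explaining all incompatibilities
#'
#' Treats sites as vertices and incompatible pairs as edges of a conflict
#' graph; the minimum number of sites whose removal explains every
#' four-gamete violation is an exact minimum vertex cover, found by branch
#' and bound with a deterministic tie-break (the lexicographically smallest
#' cover among minimum covers, sites in ascending order).
#'
#' @param aln A `cen_alignment`.
#' @param region `NULL` or `c(start, end)`.
#' @param max_vertices Tractability cap on conflict-graph vertices (default
#'   32); above it an error advises splitting the region.
#' @return List: `sites` (sorted column indices of the cover, full-alignment
#'   coordinates), `k_obs`, `n_conflict_vertices`, `pairs` (the
#'   incompatible pairs used).
#' @export
min_homoplasy_set <- function(aln, region = NULL, max_vertices = 32L) {
  pairs <- incompatible_pairs(aln, region)
  if (nrow(pairs) == 0L) {
    return(list(sites = integer(0), k_obs = 0L, n_conflict_vertices = 0L,
                pairs = pairs))
  }
  verts <- sort(unique(c(pairs$site_a, pairs$site_b)))
  if (length(verts) > max_vertices) {
    stop(sprintf(
      "tractability error: conflict graph has %d vertices (cap %d); split the region",
      length(verts), max_vertices
    ))
  }
  edges <- cbind(pairs$site_a, pairs$site_b)
  k <- .min_cover_size(edges)
  cover <- sort(.lex_min_cover(edges, k))
  list(sites = cover, k_obs = as.integer(k),
       n_conflict_vertices = length(verts), pairs = pairs)
}

#' Randomization null for the number of homoplasious sites
#'
#' Under the null of repeat mutation with no recombination, mutations are
#' placed uniformly at random among `L` sites. The default (`model =
#' "distinct"`) places mutations one at a time until `S` distinct sites have
#' been hit, mirroring an observed count of `S` segregating sites; `model =
#' "total"` places exactly `S` mutations. A replicate's homoplasious-site
#' count is the number of sites hit at least twice, and the empirical
#' p-value uses the add-one convention
#' `p = (1 + #\{count >= k_obs\}) / (n_reps + 1)`.
#'
#' @param L Region length in analysed sites.
#' @param S Number of segregating sites (S <= L).
#' @param k_obs Observed minimum number of homoplasious sites.
#' @param n_reps Replicates (default 1000).
#' @param seed Integer RNG seed.
#' @param model `"distinct"` (default) or `"total"`.
#' @return List: `p_value`, `k_obs`, `null_counts` (per-replicate counts),
#'   `n_reps`, `seed`, `model`.
#' @export
homoplasy_null_pvalue <- function(L, S, k_obs, n_reps = 1000L, seed = 1L,
                                  model = c("distinct", "total")) {
  model <- match.arg(model)
  if (S > L) stop("input error: S > L")
  stopifnot(n_reps >= 1L, L >= 1L, S >= 0L, k_obs >= 0L)
  counts <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      if (S == 0L) return(0L)
      if (model == "total") {
        hits <- tabulate(sample.int(L, S, replace = TRUE), nbins = L)
        return(sum(hits >= 2L))
      }
      draws <- integer(0)
      repeat {
        draws <- c(draws, sample.int(L, S, replace = TRUE))
        cumdist <- cumsum(!duplicated(draws))
        stop_at <- match(S, cumdist)
        if (!is.na(stop_at)) {
          draws <- draws[seq_len(stop_at)]
          break
        }
      }
      hits <- tabulate(draws, nbins = L)
      sum(hits >= 2L)
    }, integer(1))
  })
  p <- (1 + sum(counts >= k_obs)) / (n_reps + 1)
  list(p_value = p, k_obs = as.integer(k_obs), null_counts = counts,
       n_reps = as.integer(n_reps), seed = as.integer(seed), model = model)
}

#' Re-run the four-gamete test after masking putative homoplasious sites
#'
#' The removed columns are masked to `N` and the full locus (typically
#' centromere plus flanks) is re-tested; an empty result means the removed
#' sites explain all incompatibilities.
#'
#' @param aln A `cen_alignment`.
#' @param removed Integer vector of column indices to mask.
#' @param region Optional `c(start, end)` restriction for the re-test.
#' @return [incompatible_pairs()] output on the masked alignment.
#' @export
retest_after_removal <- function(aln, removed, region = NULL) {
  mat <- aln$mat
  if (length(removed)) {
    stopifnot(all(removed >= 1L & removed <= ncol(mat)))
    mat[, removed] <- "N"
  }
  masked <- cen_alignment(mat, locus_id = aln$locus_id, normalize = FALSE)
  incompatible_pairs(masked, region)
}

#' Full recombination/homoplasy analysis of one region
#'
#' Runs the four-gamete test, the Hudson-Kaplan bound, the exact
#' minimum-homoplasy-set search and the randomization null, and verifies
#' that removing the inferred set clears all incompatibilities within the
#' region.
#'
#' @inheritParams min_homoplasy_set
#' @inheritParams homoplasy_null_pvalue
#' @return List of class `homoplasy_result`: `locus_id`, `region`,
#'   `incompatible_pairs`, `rmin`, `min_homoplasy_set`, `k_obs`,
#'   `n_conflict_vertices`, `p_value`, `n_reps`, `seed`, `model`, `S`,
#'   `n_sites_analysed`.
#' @export
homoplasy_analysis <- function(aln, region = NULL, n_reps = 1000L, seed = 1L,
                               max_vertices = 32L,
                               model = c("distinct", "total")) {
  model <- match.arg(model)
  ps <- polymorphism_summary(aln, region)
  mhs <- min_homoplasy_set(aln, region, max_vertices = max_vertices)
  null <- if (ps$S > 0L && ps$n_sites_analysed > 0L) {
    homoplasy_null_pvalue(ps$n_sites_analysed, ps$S, mhs$k_obs,
                          n_reps = n_reps, seed = seed, model = model)
  } else {
    list(p_value = 1, n_reps = as.integer(n_reps))
  }
  out <- list(
    locus_id = aln$locus_id, region = region,
    incompatible_pairs = mhs$pairs,
    rmin = hudson_kaplan_rmin(mhs$pairs),
    min_homoplasy_set = mhs$sites,
    k_obs = mhs$k_obs,
    n_conflict_vertices = mhs$n_conflict_vertices,
    p_value = null$p_value,
    n_reps = as.integer(n_reps), seed = as.integer(seed), model = model,
    S = ps$S, n_sites_analysed = ps$n_sites_analysed
  )
  class(out) <- "homoplasy_result"
  out
}

#' @export
print.homoplasy_result <- function(x, ...) {
  reg <- if (is.null(x$region)) "whole" else paste(x$region, collapse = "-")
  cat(sprintf(
    "%s [%s]: S = %d, %d incompatible pairs, R_min = %d, k_obs = %d, p = %.3g\n",
    x$locus_id, reg, x$S, nrow(x$incompatible_pairs), x$rmin, x$k_obs,
    x$p_value
  ))
  invisible(x)
}
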