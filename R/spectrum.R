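# The 12 directed substitution types and their complement-collapsed classes.
SUB_TYPES <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
               "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")

# Six strand-symmetric classes, written source-pair > target-pair.
SPECTRUM_CLASSES <- c("A:T>C:G", "A:T>G:C", "A:T>T:A",
                      "C:G>A:T", "C:G>G:C", "C:G>T:A")

# directed type -> collapsed class
TYPE_TO_CLASS <- c(
  "A>C" = "A:T>C:G", "T>G" = "A:T>C:G",
  "A>G" = "A:T>G:C", "T>C" = "A:T>G:C",
  "A>T" = "A:T>T:A", "T>A" = "A:T>T:A",
  "C>A" = "C:G>A:T", "G>T" = "C:G>A:T",
  "C>G" = "C:G>G:C", "G>C" = "C:G>G:C",
  "C>T" = "C:G>T:A", "G>A" = "C:G>T:A"
)

TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")

#' Is a substitution a transition?
#' @param from,to Bases in `A C G T`.
#' @return Logical vector; `TRUE` for A<->G and C<->T.
#' @export
is_transition <- function(from, to) {
  paste0(from, ">", to) %in% TRANSITIONS
}

#' Polarize point substitutions by the unique-haplotype rule
#'
#' With no usable outgroup, an allele carried by exactly one haplotype is
#' assumed derived. Run on a haplotype-reduced alignment
#' ([reduce_to_haplotypes()]): at each column with at least three valid
#' haplotypes, exactly two distinct bases, and a singleton minor allele, the
#' change major -> minor is emitted. Columns with three or more alleles, a
#' two-way tie, or fewer than three valid haplotypes are skipped (tallied in
#' the `skipped` attribute). The >= 3 requirement is forced by the rule
#' itself: with two haplotypes both alleles are unique and polarity is
#' undefined.
#'
#' @param reduced A haplotype-reduced `cen_alignment`.
#' @param region Optional `c(start, end)` restriction.
#' @return data.frame of class `polarized_changes`: `locus_id`, `column`
#'   (full-alignment coordinates), `from`, `to`, `carrier`, `kind`
#'   (`transition`/`transversion`).
#' @export
polarize_unique_changes <- function(reduced, region = NULL) {
  mat <- reduced$mat
  offset <- 0L
  if (!is.null(region)) {
    stopifnot(region[1] >= 1L, region[2] <= ncol(mat), region[1] <= region[2])
    offset <- region[1] - 1L
    mat <- mat[, region[1]:region[2], drop = FALSE]
  }
  counts <- .base_counts(mat)
  n <- colSums(counts)
  distinct <- colSums(counts > 0L)
  minc <- apply(counts, 2L, function(x) min(x[x > 0L], Inf))
  usable <- n >= 3L & distinct == 2L & minc == 1L
  skipped <- c(
    too_few_valid = sum(n < 3L & distinct >= 2L),
    multiallelic = sum(n >= 3L & distinct >= 3L),
    tied = sum(n >= 3L & distinct == 2L & minc > 1L)
  )
  rows <- lapply(which(usable), function(k) {
    present <- BASES[counts[, k] > 0L]
    to <- present[counts[present, k] == 1L]
    from <- setdiff(present, to)
    col <- mat[, k]
    carrier <- reduced$strains[which(col == to)]
    data.frame(locus_id = reduced$locus_id, column = k + offset,
               from = from, to = to, carrier = carrier,
               kind = if (is_transition(from, to)) "transition" else "transversion",
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    locus_id = character(0), column = integer(0), from = character(0),
    to = character(0), carrier = character(0), kind = character(0),
    stringsAsFactors = FALSE
  )
  attr(out, "skipped") <- skipped
  class(out) <- c("polarized_changes", "data.frame")
  out
}

#' Substitution counts and base availabilities for one locus
#'
#' Tabulates the polarized changes into the 12 directed types
#' `n_{i->j}` and counts the availability `alpha_i` of each base — the total
#' number of `i` characters over all sequences of the (by default reduced)
#' alignment, which normalises for the extreme AT-richness of CDEII.
#'
#' @param reduced A haplotype-reduced `cen_alignment` (or the full alignment
#'   if availability should be counted over all strains).
#' @param changes Output of [polarize_unique_changes()] for the same locus.
#' @param region Optional `c(start, end)`: availability is counted within
#'   the region only.
#' @return List of class `spectrum_counts`: `locus_id`, `n` (named integer,
#'   12 types), `alpha` (named integer over A/C/G/T), `p` (alpha / sum),
#'   `p_AT`, `p_GC`.
#' @export
spectrum_counts <- function(reduced, changes, region = NULL) {
  if (nrow(changes) > 0L && !all(changes$locus_id == reduced$locus_id)) {
    stop("input error: changes and alignment are from different loci")
  }
  mat <- reduced$mat
  if (!is.null(region)) mat <- mat[, region[1]:region[2], drop = FALSE]
  type <- paste0(changes$from, ">", changes$to)
  n <- table(factor(type, levels = SUB_TYPES))
  n <- setNames(as.integer(n), SUB_TYPES)
  alpha <- vapply(BASES, function(b) sum(mat == b), integer(1))
  p <- alpha / sum(alpha)
  out <- list(locus_id = reduced$locus_id, n = n, alpha = alpha, p = p,
              p_AT = unname(p["A"] + p["T"]), p_GC = unname(p["C"] + p["G"]))
  class(out) <- "spectrum_counts"
  out
}

#' Pool per-locus spectrum counts
#' @param counts_list List of `spectrum_counts`.
#' @return A pooled `spectrum_counts` (locus_id `"pooled"`).
#' @export
pool_spectra <- function(counts_list) {
  n <- Reduce(`+`, lapply(counts_list, `[[`, "n"))
  alpha <- Reduce(`+`, lapply(counts_list, `[[`, "alpha"))
  p <- alpha / sum(alpha)
  out <- list(locus_id = "pooled", n = n, alpha = alpha, p = p,
              p_AT = unname(p["A"] + p["T"]), p_GC = unname(p["C"] + p["G"]))
  class(out) <- "spectrum_counts"
  out
}

# Point estimate of the six collapsed relative rates from pooled counts:
# r_class = ((n_class / sum n) / p_source_pair), rescaled to sum to one.
.relative_rates_point <- function(pooled) {
  n_class <- vapply(SPECTRUM_CLASSES, function(cl) {
    sum(pooled$n[names(TYPE_TO_CLASS)[TYPE_TO_CLASS == cl]])
  }, numeric(1))
  total <- sum(n_class)
  if (total == 0) stop("undefined-spectrum error: no polarized changes")
  p_src <- ifelse(startsWith(SPECTRUM_CLASSES, "A:T"), pooled$p_AT, pooled$p_GC)
  raw <- (n_class / total) / p_src
  raw / sum(raw)
}

#' Base-composition-normalised relative substitution rates with bootstrap CIs
#'
#' Relative rate of each collapsed class: the class's share of all polarized
#' substitutions, divided by the composition fraction of its source base
#' pair (`p_AT` or `p_GC`), rescaled so the six rates sum to one.
#' Uncertainty comes from resampling loci with replacement and recomputing
#' the pooled rates per replicate (percentile 95% CIs).
#'
#' @param counts_list List of per-locus `spectrum_counts`.
#' @param n_reps Bootstrap replicates (default 1000).
#' @param seed Integer RNG seed.
#' @return List of class `relative_rates`: `r` (named, sums to one),
#'   `ci_low`, `ci_high`, `n_class` (collapsed counts), `n_total`,
#'   `n_loci`, `n_reps`, `seed`.
#' @export
relative_rates_with_ci <- function(counts_list, n_reps = 1000L, seed = 1L) {
  if (!length(counts_list)) stop("input error: no loci")
  pooled <- pool_spectra(counts_list)
  r <- .relative_rates_point(pooled)
  n_class <- vapply(SPECTRUM_CLASSES, function(cl) {
    sum(pooled$n[names(TYPE_TO_CLASS)[TYPE_TO_CLASS == cl]])
  }, numeric(1))
  nl <- length(counts_list)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      idx <- sample.int(nl, nl, replace = TRUE)
      rep_pool <- pool_spectra(counts_list[idx])
      if (sum(rep_pool$n) == 0) return(rep(NA_real_, length(SPECTRUM_CLASSES)))
      .relative_rates_point(rep_pool)
    }, numeric(length(SPECTRUM_CLASSES)))
  })
  ci <- apply(boots, 1L, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  out <- list(
    r = r,
    ci_low = setNames(ci[1, ], SPECTRUM_CLASSES),
    ci_high = setNames(ci[2, ], SPECTRUM_CLASSES),
    n_class = n_class, n_total = sum(n_class),
    n_loci = nl, n_reps = as.integer(n_reps), seed = as.integer(seed)
  )
  class(out) <- "relative_rates"
  out
}

#' @export
print.relative_rates <- function(x, ...) {
  cat(sprintf("Relative substitution rates (%d changes, %d loci):\n",
              x$n_total, x$n_loci))
  for (cl in names(x$r)) {
    cat(sprintf("  %-8s r = %.3f (95%% CI %.3f-%.3f, n = %d)\n",
                cl, x$r[cl], x$ci_low[cl], x$ci_high[cl], x$n_class[cl]))
  }
  invisible(x)
}

# Maximal runs of a character in one row; returns start/end/length data.frame
.char_runs <- function(chars, char) {
  r <- rle(chars == char)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

#' Classify unique indels with homopolymer-run awareness
#'
#' Indel events are maximal gap runs in the haplotype-reduced alignment that
#' are unique to one haplotype (the same derived-state assumption as for
#' substitutions): a gap run whose columns carry bases in every other
#' haplotype is a deletion in the carrier; a base run in one haplotype where
#' every other haplotype is gapped is an insertion in the carrier. Columns
#' where any non-carrier haplotype is `N` make an event unpolarizable and it
#' is skipped. Single-base events falling inside a homopolymer run of
#' `min_run` or more (measured on a gap-free non-carrier sequence around the
#' event, because slippage in long runs has its own, much higher rate) are
#' diverted to the `other` bucket, as are all multi-base events.
#'
#' @param reduced A haplotype-reduced `cen_alignment`.
#' @param region Optional `c(start, end)` restriction.
#' @param min_run Homopolymer-run threshold (default 5).
#' @return List of class `indel_summary`: counts `one_bp_deletions`,
#'   `one_bp_insertions`, `other` (with sub-tallies `other_in_run` and
#'   `other_multibase`), and `events` (per-event data.frame with
#'   `in_run` context flag).
#' @export
classify_indels <- function(reduced, region = NULL, min_run = 5L) {
  mat <- reduced$mat
  offset <- 0L
  if (!is.null(region)) {
    offset <- region[1] - 1L
    mat <- mat[, region[1]:region[2], drop = FALSE]
  }
  nh <- nrow(mat)
  events <- list()
  if (nh >= 3L) {
    for (h in seq_len(nh)) {
      others <- setdiff(seq_len(nh), h)
      # candidate deletions: maximal '-' runs in h
      del <- .char_runs(mat[h, ], "-")
      for (e in seq_len(nrow(del))) {
        cols <- del$start[e]:del$end[e]
        oth <- mat[others, cols, drop = FALSE]
        if (all(oth %in% BASES)) {
          events[[length(events) + 1L]] <- list(
            carrier = reduced$strains[h], start = del$start[e],
            end = del$end[e], type = "deletion", cols = cols, row = h
          )
        }
      }
      # candidate insertions: maximal base runs in h where all others are '-'
      ins_col <- vapply(seq_len(ncol(mat)), function(j) {
        mat[h, j] %in% BASES && all(mat[others, j] == "-")
      }, logical(1))
      if (any(ins_col)) {
        r <- rle(ins_col)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (e in which(r$values)) {
          events[[length(events) + 1L]] <- list(
            carrier = reduced$strains[h], start = starts[e], end = ends[e],
            type = "insertion", cols = starts[e]:ends[e], row = h
          )
        }
      }
    }
  }
  # run context: does the event fall inside a homopolymer run >= min_run on a
  # gap-free reference? For deletions the reference is a non-carrier row; for
  # insertions the carrier row itself holds the bases.
  evaluate_run <- function(ev) {
    ref_row <- if (ev$type == "deletion") {
      cand <- setdiff(seq_len(nh), ev$row)
      cand[1]
    } else {
      ev$row
    }
    row <- mat[ref_row, ]
    keep <- row != "-"
    ungapped <- row[keep]
    # map event columns to positions in the ungapped reference
    posmap <- cumsum(keep)
    pos <- unique(posmap[ev$cols])
    pos <- pos[pos >= 1L]
    if (ev$type == "deletion") {
      # deleted bases exist in the reference at these positions
      pos <- unique(posmap[ev$cols])
    }
    prof <- homopolymer_runs(ungapped, min_len = min_run)
    if (nrow(prof$runs) == 0L || length(pos) == 0L) return(FALSE)
    any(vapply(pos, function(p) {
      any(prof$runs$start <= p & prof$runs$end >= p)
    }, logical(1)))
  }
  if (length(events)) {
    ev_df <- do.call(rbind, lapply(events, function(ev) {
      data.frame(
        locus_id = reduced$locus_id, carrier = ev$carrier,
        start = ev$start + offset, end = ev$end + offset,
        length = length(ev$cols), type = ev$type,
        in_run = evaluate_run(ev), stringsAsFactors = FALSE
      )
    }))
  } else {
    ev_df <- data.frame(locus_id = character(0), carrier = character(0),
                        start = integer(0), end = integer(0),
                        length = integer(0), type = character(0),
                        in_run = logical(0), stringsAsFactors = FALSE)
  }
  one_del <- sum(ev_df$type == "deletion" & ev_df$length == 1L & !ev_df$in_run)
  one_ins <- sum(ev_df$type == "insertion" & ev_df$length == 1L & !ev_df$in_run)
  in_run <- sum(ev_df$length == 1L & ev_df$in_run)
  multi <- sum(ev_df$length > 1L)
  out <- list(
    one_bp_deletions = one_del,
    one_bp_insertions = one_ins,
    other = in_run + multi,
    other_in_run = in_run,
    other_multibase = multi,
    events = ev_df
  )
  class(out) <- "indel_summary"
  out
}

#' Summary arithmetic for a mutation-spectrum table row
#'
#' Computes the derived columns of a spectrum comparison table from raw
#' counts: the transition:transversion frequency `ts / tv` and the
#' deletion-to-substitution frequency `one_bp_deletions / (ts + tv)`.
#'
#' @param ts,tv Transition and transversion counts.
#' @param one_bp_deletions,one_bp_insertions,other Indel counts.
#' @return One-row data.frame with the input counts plus `total_bps`,
#'   `ts_tv_freq` and `del_bps_freq`.
#' @export
spectrum_summary_row <- function(ts, tv, one_bp_deletions = 0L,
                                 one_bp_insertions = 0L, other = 0L) {
  data.frame(
    ts = ts, tv = tv, total_bps = ts + tv,
    ts_tv_freq = ts / tv,
    one_bp_deletions = one_bp_deletions,
    del_bps_freq = one_bp_deletions / (ts + tv),
    one_bp_insertions = one_bp_insertions,
    other = other
  )
}

#' Published spontaneous-mutation spectra for comparison
#'
#' Raw counts from published mutation-accumulation and reporter-gene studies
#' in budding yeast (genome-wide wild-type; URA3 and CAN1 reporter assays in
#' wild-type cells; a URA3 assay under elevated gene conversion), shipped as
#' data entry for side-by-side comparison with centromere spectra. Rows
#' flagged `wild_type` are the spontaneous baseline; the gene-conversion row
#' is the contrast.
#'
#' @return data.frame with columns `study`, `wild_type`, `ts`, `tv`,
#'   `one_bp_deletions`, `one_bp_insertions`, `other`.
#' @export
published_spectra <- function() {
  path <- system.file("extdata", "published_mutation_spectra.tsv",
                      package = "pointcen", mustWork = TRUE)
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
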