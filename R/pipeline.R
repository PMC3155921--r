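# Derive stage-specific seeds from one master seed, reproducibly and
# independently per (stage, locus). Kept below 2^31 - 1.
.derive_seed <- function(master, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729 + index * 15485863) %%
               2147483647)
}

#' Run the full centromere analysis over a set of loci
#'
#' Orchestrates the analysis stages per locus — region statistics,
#' recombination/homoplasy testing (core and flanks separately, then a
#' joint re-test after removing the inferred homoplasious sites), haplotype
#' reduction, mutation-spectrum polarization and indel classification — and
#' pools the spectrum across loci. Per-locus failures are logged and
#' isolated unless `strict`.
#'
#' @param config A list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{loci}{list of entries with `path` (FASTA), optional `locus_id`,
#'       and optional `core` = `c(start, end)` (1-based inclusive) marking
#'       the CDEII/centromere core; when absent the whole locus is the
#'       core.}
#'     \item{population_map}{optional path to a strain->population TSV.}
#'     \item{out_dir}{output directory for reports.}
#'     \item{seed}{master seed; stage seeds are derived from it.}
#'     \item{homoplasy_reps, spectrum_reps, bootstrap_reps}{replicate
#'       counts (defaults 1000, 1000, 10000).}
#'   }
#' @param strict Abort on the first per-locus error (default `FALSE`).
#' @return Invisibly, a list with `stats` (per-locus/per-region data.frame),
#'   `recombination` (per-locus/per-region data.frame), `spectrum`
#'   (`relative_rates`), `indels` (pooled `indel_summary` counts),
#'   `divergence` (data.frame or NULL), `failed` (character vector of
#'   locus ids), `manifest` (run metadata). Reports are written under
#'   `out_dir` as TSV/JSON when `out_dir` is given.
#' @export
run_pipeline <- function(config, strict = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), length(config$loci) > 0L)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  h_reps <- if (is.null(config$homoplasy_reps)) 1000L else as.integer(config$homoplasy_reps)
  s_reps <- if (is.null(config$spectrum_reps)) 1000L else as.integer(config$spectrum_reps)
  b_reps <- if (is.null(config$bootstrap_reps)) 10000L else as.integer(config$bootstrap_reps)
  pops <- if (!is.null(config$population_map)) {
    read_population_map(config$population_map)
  } else NULL

  stats_rows <- list()
  rec_rows <- list()
  spec_counts <- list()
  indel_events <- list()
  indel_tot <- c(one_bp_deletions = 0L, one_bp_insertions = 0L, other = 0L,
                 other_in_run = 0L, other_multibase = 0L)
  failed <- character(0)

  for (i in seq_along(config$loci)) {
    entry <- config$loci[[i]]
    lid <- if (!is.null(entry$locus_id)) entry$locus_id else
      sub("\\.(fa|fasta|fna)$", "", basename(entry$path), ignore.case = TRUE)
    res <- tryCatch({
      aln <- read_alignment(entry$path, locus_id = lid)
      core <- if (!is.null(entry$core)) as.integer(unlist(entry$core)) else
        c(1L, aln_length(aln))
      regions <- list(core = core)
      if (core[1] > 1L) regions$flank_left <- c(1L, core[1] - 1L)
      if (core[2] < aln_length(aln)) {
        regions$flank_right <- c(core[2] + 1L, aln_length(aln))
      }
      for (rn in names(regions)) {
        ps <- polymorphism_summary(aln, regions[[rn]])
        stats_rows[[length(stats_rows) + 1L]] <- data.frame(
          locus = lid, region = rn,
          start = regions[[rn]][1], end = regions[[rn]][2],
          n_sites = ps$n_sites_analysed, S = ps$S, pi = ps$pi,
          theta_w = ps$theta_w, stringsAsFactors = FALSE
        )
      }
      removed_all <- integer(0)
      for (rn in names(regions)) {
        hs <- homoplasy_analysis(
          aln, regions[[rn]], n_reps = h_reps,
          seed = .derive_seed(seed, paste0("homoplasy_", rn), i)
        )
        removed_all <- c(removed_all, hs$min_homoplasy_set)
        rec_rows[[length(rec_rows) + 1L]] <- data.frame(
          locus = lid, region = rn, S = hs$S,
          n_incompatible_pairs = nrow(hs$incompatible_pairs),
          rmin = hs$rmin, k_obs = hs$k_obs, p_value = hs$p_value,
          removed_sites = paste(hs$min_homoplasy_set, collapse = ","),
          stringsAsFactors = FALSE
        )
      }
      joint <- retest_after_removal(aln, removed_all)
      rec_rows[[length(rec_rows) + 1L]] <- data.frame(
        locus = lid, region = "joint_after_removal", S = NA_integer_,
        n_incompatible_pairs = nrow(joint), rmin = hudson_kaplan_rmin(joint),
        k_obs = NA_integer_, p_value = NA_real_,
        removed_sites = paste(removed_all, collapse = ","),
        stringsAsFactors = FALSE
      )
      reduced <- reduce_to_haplotypes(aln)
      changes <- polarize_unique_changes(reduced, region = regions$core)
      spec_counts[[lid]] <- spectrum_counts(reduced, changes,
                                             region = regions$core)
      ind <- classify_indels(reduced, region = regions$core)
      for (nm in names(indel_tot)) {
        indel_tot[[nm]] <- indel_tot[[nm]] + ind[[nm]]
      }
      if (nrow(ind$events)) {
        indel_events[[length(indel_events) + 1L]] <- ind$events
      }
      TRUE
    }, error = function(e) {
      if (strict) stop(e)
      message(sprintf("locus %s failed: %s", lid, conditionMessage(e)))
      FALSE
    })
    if (!isTRUE(res)) failed <- c(failed, lid)
  }

  stats_df <- do.call(rbind, stats_rows)
  rec_df <- do.call(rbind, rec_rows)
  spectrum <- if (length(spec_counts) &&
                  sum(vapply(spec_counts, function(x) sum(x$n), numeric(1))) > 0) {
    relative_rates_with_ci(spec_counts, n_reps = s_reps,
                           seed = .derive_seed(seed, "spectrum"))
  } else NULL

  core_stats <- stats_df[stats_df$region == "core", , drop = FALSE]
  pi_boot <- if (nrow(core_stats) >= 2L) {
    bootstrap_ci(core_stats$pi, "mean", n_reps = b_reps,
                 seed = .derive_seed(seed, "bootstrap"))
  } else NULL

  manifest <- list(
    package = "pointcen",
    version = as.character(utils::packageVersion("pointcen")),
    seed = seed,
    homoplasy_reps = h_reps, spectrum_reps = s_reps, bootstrap_reps = b_reps,
    n_loci = length(config$loci), failed = failed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  out <- list(stats = stats_df, recombination = rec_df, spectrum = spectrum,
              pi_bootstrap = pi_boot, indels = as.list(indel_tot),
              indel_events = if (length(indel_events))
                do.call(rbind, indel_events) else NULL,
              failed = failed, manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, name) {
      write.table(df, file.path(config$out_dir, name), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    wt(stats_df, "polymorphism.tsv")
    wt(rec_df, "recombination.tsv")
    if (!is.null(out$spectrum)) {
      sp <- out$spectrum
      wt(data.frame(class = names(sp$r), r = unname(sp$r),
                    ci_low = unname(sp$ci_low), ci_high = unname(sp$ci_high),
                    n = unname(sp$n_class)), "spectrum_rates.tsv")
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    jsonlite::write_json(out$indels, file.path(config$out_dir, "indels.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(out)
}
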