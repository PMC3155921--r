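# --- Kingman coalescent genealogy -------------------------------------------

# Simulate one coalescent tree for n samples. Time is in units of 2N
# generations (E[pairwise coalescence time] = 1, so the expected pairwise
# branch-path length is 2 and a per-site mutation rate of theta/2 per unit
# time yields E[pi] = theta). Returns parent pointers, branch lengths, and
# an ape::phylo for Newick export.
.sim_coalescent_tree <- function(n) {
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  blen <- numeric(n_nodes)
  depth <- numeric(n_nodes)   # time of each node above the present
  active <- seq_len(n)
  nxt <- n + 1L
  t <- 0
  while (length(active) > 1L) {
    k <- length(active)
    t <- t + rexp(1, rate = k * (k - 1) / 2)
    pick <- sample.int(k, 2L)
    a <- active[pick[1]]
    b <- active[pick[2]]
    parent[c(a, b)] <- nxt
    blen[a] <- t - depth[a]
    blen[b] <- t - depth[b]
    depth[nxt] <- t
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  root <- n_nodes
  # build ape phylo: tips 1..n keep their ids; internal nodes renumbered
  # n+1..2n-1 with the root first (ape convention root = n+1)
  internal <- seq.int(n + 1L, n_nodes)
  new_id <- integer(n_nodes)
  new_id[seq_len(n)] <- seq_len(n)
  new_id[root] <- n + 1L
  others <- setdiff(internal, root)
  new_id[others] <- n + 1L + seq_along(others)
  has_parent <- which(parent > 0L)
  edge <- cbind(new_id[parent[has_parent]], new_id[has_parent])
  phy <- structure(list(
    edge = edge,
    edge.length = blen[has_parent],
    tip.label = paste0("S", formatC(seq_len(n), width = 2, flag = "0")),
    Nnode = n - 1L
  ), class = "phylo")
  list(parent = parent, blen = blen, root = root, n = n, phylo = phy)
}

# Choose a target base given a source base and a 4x4 relative-rate matrix.
.pick_target <- function(from, rates) {
  w <- rates[from, ]
  w[from] <- 0
  sample(BASES, 1L, prob = w)
}

# Normalise a substitution matrix argument: NULL -> uniform; a named
# 12-vector "A>C"... -> 4x4; a 4x4 matrix passes through (diag ignored).
.sub_matrix <- function(substitution_matrix) {
  if (is.null(substitution_matrix)) {
    m <- matrix(1, 4, 4, dimnames = list(BASES, BASES))
  } else if (is.matrix(substitution_matrix)) {
    m <- substitution_matrix[BASES, BASES]
  } else {
    m <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
    for (tp in names(substitution_matrix)) {
      ft <- strsplit(tp, ">", fixed = TRUE)[[1]]
      m[ft[1], ft[2]] <- substitution_matrix[[tp]]
    }
  }
  diag(m) <- 0
  if (any(m < 0)) stop("configuration error: negative substitution rates")
  if (all(m == 0)) stop("configuration error: all substitution rates zero")
  m
}

#' Simulate a coalescent alignment with centromere-like structure
#'
#' Draws a standard n-sample Kingman genealogy (independent genealogies per
#' block when `n_crossovers > 0`, split at uniform breakpoints), places
#' mutations as a Poisson process on branches at per-site rate `theta/2` so
#' that `E[pi] = theta`, under a finite-sites model (repeat hits allowed, so
#' homoplasy arises naturally). Single-base indels are generated on terminal
#' branches at `indel_rate` per site per unit time, with the rate multiplied
#' by `slippage_multiplier` inside homopolymer runs of 5+ bp. N-masking is
#' applied last. Defaults emulate a CDEII core from a global strain panel:
#' 34 strains, 87 bp, ~95% A+T, `theta = 0.04`; fully resequenced data, so
#' no missing-data masking unless requested.
#'
#' @param n_strains Number of sampled strains (default 34).
#' @param length Alignment length in bp before insertions (default 87).
#' @param theta Expected per-site pairwise diversity (default 0.04); either
#'   a scalar or a length-`length` vector for rate heterogeneity along the
#'   locus (e.g. a fast centromere core inside slower flanks, sharing one
#'   genealogy).
#' @param base_composition Named root-base frequencies (default 95% A+T).
#' @param substitution_matrix `NULL` (uniform), a named vector over the 12
#'   directed types, or a 4x4 relative-rate matrix.
#' @param n_crossovers Number of recombination breakpoints (default 0).
#' @param indel_rate Per-site terminal-branch indel rate (default 0).
#' @param slippage_multiplier Indel rate multiplier inside homopolymer runs
#'   of 5+ bp (default 10).
#' @param missing_fraction Per-base probability of masking to `N`
#'   (default 0).
#' @param seed Integer RNG seed; same seed, byte-identical output.
#' @param locus_id Locus id of the returned alignment.
#' @return List of class `cen_sim`: `alignment` (a `cen_alignment`),
#'   `trees` (Newick, one per block), `breakpoints` (last column of each
#'   block but the final one), `mutations` (data.frame: site, from, to,
#'   node), `indels` (data.frame: strain, site, type), and the generating
#'   parameters.
#' @export
simulate_coalescent_alignment <- function(n_strains = 34L, length = 87L,
                                          theta = 0.04,
                                          base_composition = c(A = 0.475, C = 0.025,
                                                               G = 0.025, T = 0.475),
                                          substitution_matrix = NULL,
                                          n_crossovers = 0L,
                                          indel_rate = 0,
                                          slippage_multiplier = 10,
                                          missing_fraction = 0,
                                          seed = 1L,
                                          locus_id = "sim") {
  stopifnot(n_strains >= 2L, length >= 1L, all(theta >= 0),
            length(theta) %in% c(1L, length),
            missing_fraction >= 0, missing_fraction < 1)
  theta_vec <- rep_len(theta, length)
  bc <- base_composition[BASES]
  if (any(is.na(bc)) || abs(sum(bc) - 1) > 1e-8 || any(bc < 0)) {
    stop("configuration error: base_composition must be 4 non-negative fractions summing to 1")
  }
  rates <- .sub_matrix(substitution_matrix)
  withr::with_seed(seed, {
    # block structure
    if (n_crossovers > 0L) {
      if (length < n_crossovers + 1L) stop("configuration error: too many crossovers")
      bps <- sort(sample.int(length - 1L, n_crossovers))
      starts <- c(1L, bps + 1L)
      ends <- c(bps, length)
    } else {
      bps <- integer(0)
      starts <- 1L
      ends <- length
    }
    mat <- matrix(NA_character_, nrow = n_strains, ncol = length)
    trees <- character(0)
    mut_rows <- list()
    for (blk in seq_along(starts)) {
      cols <- starts[blk]:ends[blk]
      Lb <- length(cols)
      tr <- .sim_coalescent_tree(n_strains)
      trees <- c(trees, ape::write.tree(tr$phylo))
      # root sequence, then preorder propagation with mutations per branch
      seqs <- vector("list", 2L * n_strains - 1L)
      seqs[[tr$root]] <- sample(BASES, Lb, replace = TRUE, prob = bc)
      children <- split(seq_along(tr$parent)[tr$parent > 0L],
                        tr$parent[tr$parent > 0L])
      stack <- tr$root
      while (length(stack)) {
        node <- stack[length(stack)]
        stack <- stack[-length(stack)]
        kids <- children[[as.character(node)]]
        th_blk <- theta_vec[cols]
        for (kid in kids) {
          s <- seqs[[node]]
          n_mut <- rpois(1L, tr$blen[kid] * sum(th_blk) / 2)
          if (n_mut > 0L) {
            sites <- sample.int(Lb, n_mut, replace = TRUE, prob = th_blk)
            for (site in sites) {
              from <- s[site]
              to <- .pick_target(from, rates)
              s[site] <- to
              mut_rows[[length(mut_rows) + 1L]] <- data.frame(
                site = cols[site], from = from, to = to, node = kid,
                block = blk, stringsAsFactors = FALSE
              )
            }
          }
          seqs[[kid]] <- s
          if (kid > n_strains) stack <- c(stack, kid)
        }
      }
      for (i in seq_len(n_strains)) mat[i, cols] <- seqs[[i]]
      if (blk == 1L) tip_blen <- tr$blen[seq_len(n_strains)]
      else tip_blen <- tip_blen + tr$blen[seq_len(n_strains)]
    }
    strains <- paste0("S", formatC(seq_len(n_strains), width = 2, flag = "0"))
    rownames(mat) <- strains

    # terminal-branch single-base indels with homopolymer slippage
    indel_rows <- list()
    insertions <- list()  # applied after deletions, expanding columns
    if (indel_rate > 0) {
      tipmean <- tip_blen / length(starts)  # average tip branch across blocks
      for (i in seq_len(n_strains)) {
        w <- rep(1, length)
        prof <- homopolymer_runs(mat[i, ], min_len = 5L)
        if (nrow(prof$runs) > 0L) {
          for (rr in seq_len(nrow(prof$runs))) {
            w[prof$runs$start[rr]:prof$runs$end[rr]] <- slippage_multiplier
          }
        }
        lambda <- indel_rate * tipmean[i] * sum(w)
        n_ind <- rpois(1L, lambda)
        if (n_ind == 0L) next
        sites <- sample.int(length, n_ind, replace = TRUE, prob = w)
        for (site in sites) {
          if (runif(1) < 0.5) {
            if (mat[i, site] %in% BASES) {
              mat[i, site] <- "-"
              indel_rows[[length(indel_rows) + 1L]] <- data.frame(
                strain = strains[i], site = site, type = "deletion",
                stringsAsFactors = FALSE
              )
            }
          } else {
            indel_rows[[length(indel_rows) + 1L]] <- data.frame(
              strain = strains[i], site = site, type = "insertion",
              stringsAsFactors = FALSE
            )
            insertions[[length(insertions) + 1L]] <-
              list(strain = i, site = site, rec = length(indel_rows))
          }
        }
      }
    }
    mutations_df <- if (length(mut_rows)) do.call(rbind, mut_rows) else
      data.frame(site = integer(0), from = character(0), to = character(0),
                 node = integer(0), block = integer(0))
    if (length(insertions)) {
      # Expand one new column per insertion, right of the template site.
      # Processing in descending template order keeps each template index
      # valid; recorded sites to the right of an inserted column shift by 1
      # so ground truth stays in final alignment coordinates.
      ord <- order(-vapply(insertions, `[[`, numeric(1), "site"))
      for (k in ord) {
        ins <- insertions[[k]]
        newcol <- rep("-", n_strains)
        newcol[ins$strain] <- mat[ins$strain, ins$site]
        if (!(newcol[ins$strain] %in% BASES)) newcol[ins$strain] <- sample(BASES, 1L, prob = bc)
        left <- mat[, seq_len(ins$site), drop = FALSE]
        right <- if (ins$site < ncol(mat)) {
          mat[, (ins$site + 1L):ncol(mat), drop = FALSE]
        } else NULL
        mat <- cbind(left, newcol, right)
        rownames(mat) <- strains
        for (r in seq_along(indel_rows)) {
          if (indel_rows[[r]]$site > ins$site) {
            indel_rows[[r]]$site <- indel_rows[[r]]$site + 1L
          }
        }
        indel_rows[[ins$rec]]$site <- ins$site + 1L
        shift <- mutations_df$site > ins$site
        mutations_df$site[shift] <- mutations_df$site[shift] + 1L
      }
      colnames(mat) <- NULL
    }

    if (missing_fraction > 0) {
      mask <- matrix(runif(nrow(mat) * ncol(mat)) < missing_fraction,
                     nrow = nrow(mat))
      mask <- mask & (mat %in% BASES)
      mat[mask] <- "N"
    }

    aln <- cen_alignment(mat, locus_id = locus_id, normalize = FALSE)
    out <- list(
      alignment = aln,
      trees = trees,
      breakpoints = bps,
      mutations = mutations_df,
      indels = if (length(indel_rows)) do.call(rbind, indel_rows) else
        data.frame(strain = character(0), site = integer(0), type = character(0)),
      params = list(n_strains = n_strains, length = length, theta = theta,
                    base_composition = bc, n_crossovers = n_crossovers,
                    indel_rate = indel_rate,
                    slippage_multiplier = slippage_multiplier,
                    missing_fraction = missing_fraction, seed = seed)
    )
    class(out) <- "cen_sim"
    out
  })
}

#' @export
print.cen_sim <- function(x, ...) {
  cat(sprintf(
    "<cen_sim> %d strains x %d bp, theta = %g, %d mutations, %d crossovers\n",
    x$params$n_strains, ncol(x$alignment$mat), x$params$theta,
    nrow(x$mutations), x$params$n_crossovers
  ))
  invisible(x)
}

#' Plant a point centromere in random flanking sequence
#'
#' Builds `flank + CDEI instance + AT-rich CDEII + CDEIII instance + flank`
#' with known coordinates, for annotation tests. Flanks are drawn from
#' `flank_composition`; the CDEII core from `base_composition` (default 95%
#' A+T).
#'
#' @param cdei,cdeiii Concrete motif instances (defaults are instances of
#'   the shipped consensus patterns).
#' @param cdeii_length CDEII length in bp (default 87).
#' @param flank_length Flank length either side (default 200).
#' @param base_composition CDEII base frequencies.
#' @param flank_composition Flank base frequencies (default uniform 0.25).
#' @param reverse_complement Return the reverse complement (truth
#'   coordinates mirrored, strand `-`).
#' @param seed Integer RNG seed.
#' @return List: `sequence` (character string) and `truth` (one-row
#'   annotation data.frame as from [annotate_point_centromere()]).
#' @export
plant_centromere_sequence <- function(cdei = "ATCACGTG",
                                      cdeii_length = 87L,
                                      cdeiii = "TGTTTATGATTTCCGAACGTAAAAA",
                                      flank_length = 200L,
                                      base_composition = c(A = 0.475, C = 0.025,
                                                           G = 0.025, T = 0.475),
                                      flank_composition = c(A = 0.25, C = 0.25,
                                                            G = 0.25, T = 0.25),
                                      reverse_complement = FALSE,
                                      seed = 1L) {
  withr::with_seed(seed, {
    flank1 <- sample(BASES, flank_length, replace = TRUE,
                     prob = flank_composition[BASES])
    flank2 <- sample(BASES, flank_length, replace = TRUE,
                     prob = flank_composition[BASES])
    core <- sample(BASES, cdeii_length, replace = TRUE,
                   prob = base_composition[BASES])
    seq <- paste(c(flank1, strsplit(cdei, "")[[1]], core,
                   strsplit(cdeiii, "")[[1]], flank2), collapse = "")
  })
  L <- nchar(seq)
  cdei_start <- flank_length + 1L
  cdei_end <- flank_length + nchar(cdei)
  cdeii_start <- cdei_end + 1L
  cdeii_end <- cdei_end + cdeii_length
  cdeiii_start <- cdeii_end + 1L
  cdeiii_end <- cdeii_end + nchar(cdeiii)
  strand <- "+"
  if (reverse_complement) {
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    mirror <- function(s, e) c(L - e + 1L, L - s + 1L)
    ci <- mirror(cdei_start, cdei_end)
    cii <- mirror(cdeii_start, cdeii_end)
    ciii <- mirror(cdeiii_start, cdeiii_end)
    cdei_start <- ci[1]; cdei_end <- ci[2]
    cdeii_start <- cii[1]; cdeii_end <- cii[2]
    cdeiii_start <- ciii[1]; cdeiii_end <- ciii[2]
    strand <- "-"
  }
  truth <- data.frame(
    source_id = "planted", strand = strand,
    cdei_start = cdei_start, cdei_end = cdei_end,
    cdeii_start = cdeii_start, cdeii_end = cdeii_end,
    cdeiii_start = cdeiii_start, cdeiii_end = cdeiii_end,
    stringsAsFactors = FALSE
  )
  list(sequence = seq, truth = truth)
}

#' Mask alignment bases to N at random
#'
#' Emulates low-coverage shotgun data where only a fraction of sites have a
#' quality base call. Each valid base is masked to `N` independently with
#' probability `missing_fraction`; gaps are left in place.
#'
#' @param aln A `cen_alignment`.
#' @param missing_fraction Per-base masking probability in `[0, 1)`.
#' @param seed Integer RNG seed.
#' @return The degraded `cen_alignment`.
#' @export
degrade_alignment <- function(aln, missing_fraction, seed = 1L) {
  stopifnot(missing_fraction >= 0, missing_fraction < 1)
  if (missing_fraction == 0) return(aln)
  mat <- aln$mat
  mask <- withr::with_seed(seed, {
    matrix(runif(nrow(mat) * ncol(mat)) < missing_fraction, nrow = nrow(mat))
  })
  mask <- mask & (mat %in% BASES)
  mat[mask] <- "N"
  cen_alignment(mat, locus_id = aln$locus_id, normalize = FALSE)
}

#' Write a simulated locus to disk
#'
#' FASTA alignment plus a ground-truth JSON (trees in Newick, mutation list,
#' breakpoints, indels, parameters).
#'
#' @param sim A `cen_sim`.
#' @param fasta,json Output paths (either may be `NULL`).
#' @export
write_simulation <- function(sim, fasta = NULL, json = NULL) {
  if (!is.null(fasta)) write_alignment(sim$alignment, fasta)
  if (!is.null(json)) {
    truth <- list(trees = sim$trees, breakpoints = sim$breakpoints,
                  mutations = sim$mutations, indels = sim$indels,
                  params = sim$params)
    jsonlite::write_json(truth, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(sim)
}
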