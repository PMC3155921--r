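# Independent oracles and fixture builders used across the suite. These stay
# deliberately naive (enumeration / brute force) and share no code with the
# implementation they check.

BASES4 <- c("A", "C", "G", "T")

# Random alignment with optional N / gap contamination.
random_alignment <- function(n, L, p_missing = 0.2, p_gap = 0.05,
                             locus_id = "rand") {
  chars <- sample(c(BASES4, "N", "-"), n * L, replace = TRUE,
                  prob = c(rep((1 - p_missing - p_gap) / 4, 4),
                           p_missing, p_gap))
  mat <- matrix(chars, nrow = n)
  rownames(mat) <- sprintf("s%02d", seq_len(n))
  cen_alignment(mat, locus_id = locus_id, normalize = FALSE)
}

# Brute-force nucleotide diversity: per analysed site (>= 2 valid bases),
# the mean difference indicator over all valid pairs; averaged over
# analysed sites.
brute_pi <- function(aln) {
  mat <- aln$mat
  per_site <- numeric(0)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    v <- col[col %in% BASES4]
    if (length(v) < 2L) next
    pairs <- combn(length(v), 2)
    per_site <- c(per_site, mean(v[pairs[1, ]] != v[pairs[2, ]]))
  }
  if (!length(per_site)) return(0)
  mean(per_site)
}

# Brute-force Dxy by explicit pair enumeration per site.
brute_dxy <- function(aln, pops, pa, pb) {
  mat <- aln$mat
  ra <- which(rownames(mat) %in% names(pops)[pops == pa])
  rb <- which(rownames(mat) %in% names(pops)[pops == pb])
  per_site <- numeric(0)
  for (j in seq_len(ncol(mat))) {
    va <- mat[ra, j][mat[ra, j] %in% BASES4]
    vb <- mat[rb, j][mat[rb, j] %in% BASES4]
    if (!length(va) || !length(vb)) next
    diffs <- outer(va, vb, `!=`)
    per_site <- c(per_site, mean(diffs))
  }
  mean(per_site)
}

# Exhaustive minimum vertex cover over <= 16 local vertices via bitmask
# enumeration. edges: 2-column matrix of vertex labels.
exhaustive_min_cover_size <- function(edges) {
  if (nrow(edges) == 0L) return(0L)
  verts <- sort(unique(c(edges[, 1], edges[, 2])))
  nv <- length(verts)
  stopifnot(nv <= 16L)
  ia <- match(edges[, 1], verts)
  ib <- match(edges[, 2], verts)
  subsets <- 0:(2^nv - 1)
  covered <- rep(TRUE, length(subsets))
  for (e in seq_len(nrow(edges))) {
    mask <- bitwOr(bitwShiftL(1L, ia[e] - 1L), bitwShiftL(1L, ib[e] - 1L))
    covered <- covered & bitwAnd(subsets, mask) > 0L
  }
  popcount <- vapply(subsets[covered], function(s) {
    sum(bitwAnd(s, bitwShiftL(1L, 0:(nv - 1L))) > 0L)
  }, numeric(1))
  as.integer(min(popcount))
}

# Brute-force minimum number of points stabbing all open intervals (a, b):
# candidate points sit just left of each right endpoint.
brute_rmin <- function(a, b) {
  if (!length(a)) return(0L)
  cand <- sort(unique(b)) - 0.5
  m <- length(a)
  for (k in 0:length(cand)) {
    if (k == 0L) {
      if (m == 0L) return(0L)
      next
    }
    combos <- combn(cand, k)
    for (c_i in seq_len(ncol(combos))) {
      pts <- combos[, c_i]
      hit <- vapply(seq_len(m), function(e) {
        any(pts > a[e] & pts < b[e])
      }, logical(1))
      if (all(hit)) return(k)
    }
  }
  length(cand)
}

# Full-enumeration two-sided binomial p-value (minimum-likelihood method).
enum_binom_p <- function(x, n, p0) {
  probs <- dbinom(0:n, n, p0)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

# Independent reading of the relative-rate formula: step-by-step divide,
# normalise by source-pair composition, rescale.
step_by_step_rates <- function(n_by_type, alpha) {
  classes <- c("A:T>C:G", "A:T>G:C", "A:T>T:A",
               "C:G>A:T", "C:G>G:C", "C:G>T:A")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  class_of <- function(from, to) {
    # canonical strand: report from the A- or C-sourced strand
    if (from %in% c("T", "G")) {
      from <- comp[[from]]
      to <- comp[[to]]
    }
    paste0(from, ":", comp[[from]], ">", to, ":", comp[[to]])
  }
  nc <- setNames(numeric(6), classes)
  for (tp in names(n_by_type)) {
    ft <- strsplit(tp, ">")[[1]]
    cl <- class_of(ft[1], ft[2])
    nc[cl] <- nc[cl] + n_by_type[[tp]]
  }
  p <- alpha / sum(alpha)
  p_src <- ifelse(substr(classes, 1, 3) == "A:T", p["A"] + p["T"],
                  p["C"] + p["G"])
  frac <- nc / sum(nc)
  raw <- frac / p_src
  raw / sum(raw)
}

# Write an alignment as a FASTA tempfile and return the path.
fasta_tempfile <- function(seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(seqs), function(n) {
    c(paste0(">", n), seqs[[n]])
  })), path)
  path
}
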