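#' Construct a per-locus multiple sequence alignment
#'
#' The central container of the package: a character matrix with one row per
#' strain and one column per alignment position, over the six-letter alphabet
#' `A C G T N -` ('N' = missing/ambiguous base, '-' = alignment gap).
#'
#' @param seqs Named character vector of aligned sequences (names are strain
#'   ids), or a character matrix with rownames.
#' @param locus_id Locus identifier.
#' @param normalize If `TRUE` (default), case-fold to upper and map any
#'   character outside `A C G T -` to `N`. The number of substituted
#'   characters is recorded in the `n_normalized` attribute.
#' @return An object of class `cen_alignment`: a list with elements
#'   `locus_id`, `strains`, and `mat` (character matrix, rows = strains).
#' @export
cen_alignment <- function(seqs, locus_id = "locus", normalize = TRUE) {
  if (is.matrix(seqs)) {
    mat <- seqs
    if (is.null(rownames(mat))) stop("matrix input requires rownames")
  } else {
    if (length(seqs) == 0L) stop("alignment must contain at least one record")
    if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
      stop("all sequences must be named by strain id")
    }
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      stop(sprintf(
        "alignment-shape error in '%s': sequence lengths differ (%s)",
        locus_id, paste(unique(lens), collapse = ", ")
      ))
    }
    if (lens[1] < 1L) stop("alignment length must be >= 1")
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(mat) <- names(seqs)
  }
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate strain ids in alignment")
  }
  n_norm <- 0L
  if (normalize) {
    mat[] <- toupper(mat)
    bad <- !(mat %in% ALN_ALPHABET)
    n_norm <- sum(bad)
    if (n_norm > 0L) mat[bad] <- "N"
  } else if (any(!(mat %in% ALN_ALPHABET))) {
    stop("characters outside the A/C/G/T/N/- alphabet")
  }
  structure(
    list(locus_id = locus_id, strains = rownames(mat), mat = mat),
    n_normalized = n_norm,
    class = "cen_alignment"
  )
}

#' @export
print.cen_alignment <- function(x, ...) {
  cat(sprintf(
    "<cen_alignment> locus '%s': %d strains x %d columns\n",
    x$locus_id, nrow(x$mat), ncol(x$mat)
  ))
  invisible(x)
}

#' Number of alignment columns
#' @param aln A `cen_alignment`.
#' @export
aln_length <- function(aln) ncol(aln$mat)

#' Read a per-locus alignment from FASTA
#'
#' Sequences are case-folded to upper; any character outside `A C G T -`
#' (including IUPAC ambiguity codes) becomes `N`, with the substitution count
#' reported via a message and kept in the `n_normalized` attribute.
#'
#' @param path Path to a FASTA file with >= 1 equal-length records.
#' @param locus_id Locus identifier; defaults to the file name without
#'   extension.
#' @return A `cen_alignment`.
#' @export
read_alignment <- function(path, locus_id = NULL) {
  if (is.null(locus_id)) {
    locus_id <- sub("\\.(fa|fasta|fna)$", "", basename(path), ignore.case = TRUE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("input error: empty FASTA '%s'", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop(sprintf("input error: duplicate FASTA headers in '%s'", path))
  }
  seqs <- setNames(as.character(set), ids)
  aln <- cen_alignment(seqs, locus_id = locus_id)
  n_norm <- attr(aln, "n_normalized")
  if (n_norm > 0L) {
    message(sprintf(
      "%s: %d non-ACGT/- characters normalized to N", locus_id, n_norm
    ))
  }
  aln
}

#' Write an alignment to FASTA (wrapped at 60 columns)
#' @param aln A `cen_alignment`.
#' @param path Output path.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln$mat, 1L, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- aln$strains
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a strain-to-population assignment table
#'
#' @param path TSV with two columns: strain id and population label (a header
#'   line is auto-detected when its first field is `strain`).
#' @return Named character vector mapping strain id -> population.
#' @export
read_population_map <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (ncol(tab) < 2L) stop("population map needs two columns")
  if (identical(tolower(tab[1, 1]), "strain")) tab <- tab[-1, , drop = FALSE]
  setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' Bases observed at one alignment column
#'
#' `N` and `-` are excluded: indels and sub-threshold-quality calls are
#' treated as missing data, so only unambiguous bases enter any statistic.
#'
#' @param aln A `cen_alignment`.
#' @param column 1-based column index.
#' @return Named integer vector of counts over the bases present (subset of
#'   A/C/G/T; empty when no strain has a valid base), with a `strains`
#'   attribute giving per-strain provenance (named character vector of the
#'   valid bases).
#' @export
site_states <- function(aln, column) {
  if (column < 1L || column > ncol(aln$mat)) {
    stop(sprintf("bounds error: column %d outside 1..%d", column, ncol(aln$mat)))
  }
  col <- aln$mat[, column]
  valid <- col %in% BASES
  bases <- col[valid]
  counts <- table(factor(bases, levels = BASES))
  out <- as.integer(counts)[counts > 0]
  names(out) <- names(counts)[counts > 0]
  attr(out, "strains") <- setNames(bases, aln$strains[valid])
  out
}

# TRUE where the two base vectors are compatible under wildcard matching:
# agree at every column where both are in {A,C,G,T,-}; N matches anything.
.compatible <- function(a, b) {
  both <- a != "N" & b != "N"
  all(a[both] == b[both])
}

#' Collapse an alignment to one representative per haplotype
#'
#' Two sequences belong to the same haplotype class iff they agree at every
#' column where both carry a determinate state (`A C G T` or `-`; the gap is
#' a fifth matchable state so indel haplotypes stay distinct, while `N` is a
#' wildcard). Because wildcard compatibility is not transitive, classes are
#' formed greedily and deterministically: strains are sorted by number of
#' non-N characters (descending; ties broken by strain id, C-locale), seeded
#' as class representatives in that order, and each strain joins the first
#' class whose representative it is compatible with. The representative is
#' therefore always the least-ambiguous member of its class.
#'
#' @param aln A `cen_alignment`.
#' @return A `cen_alignment` of representatives (strain ids `H1`, `H2`, ...)
#'   with attributes `classes` (data.frame: haplotype_id, representative,
#'   members, n_unambiguous) and `members` (named list haplotype_id ->
#'   member strain ids).
#' @export
reduce_to_haplotypes <- function(aln) {
  mat <- aln$mat
  n_unamb <- rowSums(mat != "N")
  ord <- order(-n_unamb, rownames(mat), method = "radix")
  reps <- integer(0)           # row indices of representatives, in seed order
  membership <- integer(nrow(mat))
  for (i in ord) {
    assigned <- FALSE
    for (k in seq_along(reps)) {
      if (.compatible(mat[i, ], mat[reps[k], ])) {
        membership[i] <- k
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      membership[i] <- length(reps)
    }
  }
  hap_ids <- paste0("H", seq_along(reps))
  red_mat <- mat[reps, , drop = FALSE]
  rownames(red_mat) <- hap_ids
  members <- lapply(seq_along(reps), function(k) {
    sort(rownames(mat)[membership == k], method = "radix")
  })
  names(members) <- hap_ids
  classes <- data.frame(
    haplotype_id = hap_ids,
    representative = rownames(mat)[reps],
    members = vapply(members, paste, character(1), collapse = ","),
    n_unambiguous = n_unamb[reps],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  out <- cen_alignment(red_mat, locus_id = aln$locus_id, normalize = FALSE)
  attr(out, "classes") <- classes
  attr(out, "members") <- members
  out
}

#' Write a haplotype-class report as TSV
#' @param reduced Output of [reduce_to_haplotypes()].
#' @param path Output path.
#' @export
write_haplotype_report <- function(reduced, path) {
  classes <- attr(reduced, "classes")
  if (is.null(classes)) stop("not a reduced alignment")
  write.table(classes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
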