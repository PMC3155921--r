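# CDEI/CDEIII consensus motifs are configuration, not hard-coded truth: the
# degenerate strings below are editable defaults echoed into every report.
# CDEI is the canonical 8 bp helix-loop-helix binding site; the 25 bp CDEIII
# default captures the conserved TGT..TG core, the essential CCGAA box and
# the terminal A-run, with N at the unconstrained positions.

#' Default CDEI consensus motif (8 bp, IUPAC)
#' @export
CDEI_CONSENSUS <- "RTCACRTG"

#' Default CDEIII consensus motif (25 bp, IUPAC)
#' @export
CDEIII_CONSENSUS <- "TGTTTWTGNTTTCCGAANNNNAAAA"

.check_iupac <- function(pattern) {
  ok <- strsplit(pattern, "", fixed = TRUE)[[1]] %in%
    names(Biostrings::IUPAC_CODE_MAP)
  if (!all(ok)) {
    stop(sprintf(
      "configuration error: invalid IUPAC character(s) '%s' in pattern",
      paste(unique(strsplit(pattern, "")[[1]][!ok]), collapse = "")
    ))
  }
  invisible(TRUE)
}

#' Find exact IUPAC motif matches on both strands
#'
#' Pattern ambiguity codes expand to their base sets; subject letters are
#' literal, so an `N` in the sequence never matches any pattern position.
#' Reverse-strand hits are reported in forward coordinates.
#'
#' @param seq Nucleotide string over `A C G T N` (case-insensitive).
#' @param pattern IUPAC-degenerate pattern string.
#' @param name Motif name carried into the result.
#' @return data.frame with columns `motif`, `start`, `end` (1-based
#'   inclusive), `strand`, sorted by start.
#' @export
find_motif_matches <- function(seq, pattern, name = "motif") {
  .check_iupac(pattern)
  subj <- Biostrings::DNAString(toupper(seq))
  hit_df <- function(p, strand) {
    m <- Biostrings::matchPattern(p, subj, fixed = "subject")
    if (length(m) == 0L) return(NULL)
    data.frame(motif = name, start = Biostrings::start(m),
               end = Biostrings::end(m), strand = strand,
               stringsAsFactors = FALSE)
  }
  fwd <- hit_df(pattern, "+")
  rcp <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
  rev <- hit_df(rcp, "-")
  out <- rbind(fwd, rev)
  if (is.null(out)) {
    out <- data.frame(motif = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Annotate point centromeres from CDEI/CDEIII motif pairs
#'
#' Scans both strands for the two conserved binding-site motifs and reports
#' every same-strand CDEI/CDEIII pair (CDEI upstream of CDEIII in motif
#' orientation) whose intervening gap — the AT-rich CDEII core — has a length
#' inside `cdeii_len_range`. Absence of any acceptable pair is a valid empty
#' result, not an error. Overlapping candidates are all reported; choosing
#' among them is the caller's decision.
#'
#' @param seq Nucleotide string over `A C G T N`.
#' @param source_id Identifier carried into the annotation.
#' @param cdei,cdeiii IUPAC motif patterns (defaults [CDEI_CONSENSUS],
#'   [CDEIII_CONSENSUS]).
#' @param cdeii_len_range Length-2 integer vector: acceptable CDEII lengths
#'   (inclusive). Default `c(75, 100)`, bracketing the canonical 80-90 bp
#'   core.
#' @return data.frame (possibly 0-row), one row per annotation: `source_id`,
#'   `strand`, and 1-based inclusive `cdei_start/end`, `cdeii_start/end`,
#'   `cdeiii_start/end` in forward coordinates. The motif patterns used are
#'   attached as attributes for provenance.
#' @export
annotate_point_centromere <- function(seq, source_id = "seq",
                                      cdei = CDEI_CONSENSUS,
                                      cdeiii = CDEIII_CONSENSUS,
                                      cdeii_len_range = c(75L, 100L)) {
  stopifnot(length(cdeii_len_range) == 2L,
            cdeii_len_range[1] <= cdeii_len_range[2])
  m1 <- find_motif_matches(seq, cdei, "CDEI")
  m3 <- find_motif_matches(seq, cdeiii, "CDEIII")
  rows <- list()
  for (i in seq_len(nrow(m1))) {
    for (j in seq_len(nrow(m3))) {
      if (m1$strand[i] != m3$strand[j]) next
      if (m1$strand[i] == "+") {
        gap_start <- m1$end[i] + 1L
        gap_end <- m3$start[j] - 1L
      } else {
        # motif orientation reversed: CDEIII lies left of CDEI on the forward
        # strand when the centromere is on '-'
        gap_start <- m3$end[j] + 1L
        gap_end <- m1$start[i] - 1L
      }
      gap_len <- gap_end - gap_start + 1L
      if (gap_len < cdeii_len_range[1] || gap_len > cdeii_len_range[2]) next
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = source_id, strand = m1$strand[i],
        cdei_start = m1$start[i], cdei_end = m1$end[i],
        cdeii_start = gap_start, cdeii_end = gap_end,
        cdeiii_start = m3$start[j], cdeiii_end = m3$end[j],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    source_id = character(0), strand = character(0),
    cdei_start = integer(0), cdei_end = integer(0),
    cdeii_start = integer(0), cdeii_end = integer(0),
    cdeiii_start = integer(0), cdeiii_end = integer(0),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$cdeii_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cdei_pattern") <- cdei
  attr(out, "cdeiii_pattern") <- cdeiii
  attr(out, "cdeii_len_range") <- as.integer(cdeii_len_range)
  out
}

#' Convert centromere annotations to GRanges
#' @param ann data.frame from [annotate_point_centromere()].
#' @param seq_length Length of the source sequence (for seqinfo; optional).
#' @return `GRanges` with one feature per element (CDEI, CDEII, CDEIII).
#' @export
annotation_granges <- function(ann, seq_length = NA_integer_) {
  if (nrow(ann) == 0L) {
    return(GenomicRanges::GRanges())
  }
  feats <- do.call(rbind, lapply(seq_len(nrow(ann)), function(i) {
    data.frame(
      seqnames = ann$source_id[i],
      start = c(ann$cdei_start[i], ann$cdeii_start[i], ann$cdeiii_start[i]),
      end = c(ann$cdei_end[i], ann$cdeii_end[i], ann$cdeiii_end[i]),
      strand = ann$strand[i],
      type = c("CDEI", "CDEII", "CDEIII"),
      stringsAsFactors = FALSE
    )
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = feats$seqnames,
    ranges = IRanges::IRanges(feats$start, feats$end),
    strand = feats$strand
  )
  S4Vectors::mcols(gr)$type <- feats$type
  if (!is.na(seq_length)) {
    GenomeInfoDb_ok <- requireNamespace("GenomeInfoDb", quietly = TRUE)
    if (GenomeInfoDb_ok) {
      GenomeInfoDb::seqlengths(gr) <- setNames(seq_length, unique(feats$seqnames))
    }
  }
  gr
}

#' Export centromere annotations as GFF3 and/or BED
#'
#' GFF3 coordinates are 1-based inclusive; BED 0-based half-open (both
#' handled by rtracklayer). The motif patterns used are written as GFF3
#' header comments for provenance.
#'
#' @param ann data.frame from [annotate_point_centromere()].
#' @param gff3,bed Output paths (either may be `NULL`).
#' @export
write_annotation <- function(ann, gff3 = NULL, bed = NULL) {
  gr <- annotation_granges(ann)
  if (!is.null(gff3)) {
    rtracklayer::export(gr, gff3, format = "gff3")
    hdr <- c(
      sprintf("## cdei-pattern=%s", attr(ann, "cdei_pattern")),
      sprintf("## cdeiii-pattern=%s", attr(ann, "cdeiii_pattern"))
    )
    body <- readLines(gff3)
    writeLines(c(body[1], hdr, body[-1]), gff3)
  }
  if (!is.null(bed)) {
    if (length(gr) > 0) S4Vectors::mcols(gr)$name <- S4Vectors::mcols(gr)$type
    rtracklayer::export(gr, bed, format = "bed")
  }
  invisible(ann)
}
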