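#' Assign footprints to ribosomal A-, P- and E-site codons
#'
#' Converts footprint alignments into codon-level ribosome positions
#' using frame-dependent 5'-end offsets. For footprints whose 5' end lies
#' in frame 0 (codon-aligned), the A-site codon occupies footprint
#' positions 16-18 (1-based), i.e. an offset of 15 nt from the 5' end;
#' for 5' ends in the -1 frame the A-site occupies positions 17-19
#' (offset 16 nt). Footprints with 5' ends in the +1 frame have no
#' defined A-site under this rule and are discarded (but counted).
#'
#' @param alignments data.frame with `transcript_id`, `five_prime`
#'   (0-based), `length` (nt).
#' @param transcripts a [transcriptome]; unknown transcript ids are a
#'   hard error.
#' @param long_range,short_range inclusive footprint-length ranges (nt)
#'   defining the long and short footprint classes. Defaults are the
#'   dominant human classes: 29-31 nt (long) and 21-22 nt (short). Pass
#'   e.g. `long_range = c(28, 32)` for the wider class used when building
#'   count matrices, or species-specific ranges (30-32 nt mouse, 27-29 nt
#'   yeast). Lengths outside both ranges are discarded and counted.
#'
#' @return A data.frame of class `site_assignments` with columns
#'   `transcript_id`, `five_prime`, `length`, `footprint_class`
#'   (`"long"`/`"short"`), `frame_class` (`"frame0"`/`"frameMinus1"`),
#'   `a_site_codon`, `p_site_codon`, `e_site_codon` (0-based codon
#'   indices relative to `cds_start`; the P and E sites trail the A site
#'   by one and two codons). Attribute `dropped` counts discarded
#'   footprints by reason (`length`, `frame_plus1`, `out_of_bounds`).
#'
#' @details A-site codon indices may be negative (initiation context /
#'   5' UTR) or reach beyond the last codon (termination context);
#'   assignments more than 6 codons outside the CDS - beyond the 18-nt
#'   UTR extension used for mapping - are dropped as `out_of_bounds`.
#'   Both footprint classes use the same 5'-anchored offsets; see the
#'   package vignette for the rationale.
#' @export
assign_sites <- function(alignments, transcripts,
                         long_range = c(29L, 31L),
                         short_range = c(21L, 22L)) {
  stopifnot(inherits(transcripts, "transcriptome"))
  i <- .tx_index(transcripts, alignments$transcript_id)
  cs <- transcripts$anno$cds_start[i]
  L <- transcripts$anno$cds_codons[i]
  len <- as.integer(alignments$length)
  is_long <- len >= long_range[1L] & len <= long_range[2L]
  is_short <- len >= short_range[1L] & len <= short_range[2L]
  in_class <- is_long | is_short
  rel <- as.integer(alignments$five_prime) - cs
  frame <- rel %% 3L
  ok_frame <- frame != 1L
  # frame 0: A-site offset 15 nt; frame -1 (rel mod 3 == 2): offset 16 nt.
  # Both make rel + offset divisible by 3, so the division is exact.
  a <- integer(length(rel))
  a[frame == 0L] <- (rel[frame == 0L] + 15L) %/% 3L
  a[frame == 2L] <- (rel[frame == 2L] + 16L) %/% 3L
  in_bounds <- a >= -6L & a <= L + 6L
  keep <- in_class & ok_frame & in_bounds
  out <- data.frame(
    transcript_id = alignments$transcript_id[keep],
    five_prime = alignments$five_prime[keep],
    length = len[keep],
    footprint_class = ifelse(is_long[keep], "long", "short"),
    frame_class = ifelse(frame[keep] == 0L, "frame0", "frameMinus1"),
    a_site_codon = a[keep],
    stringsAsFactors = FALSE)
  out$p_site_codon <- out$a_site_codon - 1L
  out$e_site_codon <- out$a_site_codon - 2L
  attr(out, "dropped") <- c(
    length = sum(!in_class),
    frame_plus1 = sum(in_class & !ok_frame),
    out_of_bounds = sum(in_class & ok_frame & !in_bounds))
  class(out) <- c("site_assignments", "data.frame")
  out
}

#' Write site assignments as TSV
#'
#' @param assignments a `site_assignments` data.frame from
#'   [assign_sites()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_assignments <- function(assignments, path) {
  .write_tsv(assignments[, c("transcript_id", "five_prime", "length",
                             "footprint_class", "frame_class",
                             "a_site_codon")], path)
}
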