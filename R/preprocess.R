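#' Clip the 3' adapter and trim the randomized linker
#'
#' Raw reads are laid out as `insert + NNNN + adapter`: the sequencing
#' library attaches a 3' linker whose first four positions are randomized
#' (to reduce ligation bias) followed by a constant adapter sequence.
#' Clipping removes everything from the first (left-most) exact occurrence
#' of the constant adapter onwards, then trims the four randomized
#' nucleotides immediately upstream of it.
#'
#' @param reads character vector of raw read sequences (names, if any,
#'   are preserved on the kept reads).
#' @param adapter constant adapter sequence (non-empty nucleotide string).
#' @param min_insert,max_insert retained insert length bounds in nt;
#'   inserts outside `[min_insert, max_insert]` are dropped. The defaults
#'   keep 15-35 nt, below the shortest informative footprint and above the
#'   widest gel cut.
#'
#' @return A list with `reads` (the retained insert sequences) and
#'   `dropped`, a named integer vector counting reads discarded because
#'   the adapter was not found (`no_adapter`), the insert was too short
#'   (`too_short`) or too long (`too_long`).
#' @export
clip_and_trim <- function(reads, adapter, min_insert = 15L, max_insert = 35L) {
  if (!is.character(adapter) || length(adapter) != 1L || !nzchar(adapter))
    stop("adapter must be a non-empty string")
  nms <- names(reads)
  reads <- as.character(reads)
  pos <- regexpr(adapter, reads, fixed = TRUE)
  ins_len <- as.integer(pos) - 1L - 4L   # prefix before adapter, minus NNNN
  no_adapter <- pos < 0L
  too_short <- !no_adapter & ins_len < min_insert
  too_long <- !no_adapter & ins_len > max_insert
  keep <- !no_adapter & !too_short & !too_long
  out <- substr(reads[keep], 1L, ins_len[keep])
  names(out) <- nms[keep]
  list(reads = out,
       dropped = c(no_adapter = sum(no_adapter),
                   too_short = sum(too_short),
                   too_long = sum(too_long)))
}

#' Map processed reads exactly and uniquely to a transcriptome
#'
#' A deterministic exact-substring mapper for error-free (synthetic)
#' reads. A read is reported only if it matches at exactly one location
#' across all transcripts; reads with no match or with two or more match
#' locations (in one or several transcripts) are dropped and counted,
#' mirroring the unique-mapping filter applied to real libraries.
#'
#' @param reads character vector of processed read sequences.
#' @param transcripts a [transcriptome].
#'
#' @return A list with `alignments` (data.frame `transcript_id`,
#'   `five_prime` 0-based, `length`) in input read order, and `dropped`
#'   (named counts `unmapped`, `multimapped`).
#'
#' @details Matching uses [Biostrings::matchPDict()] against the
#'   transcript set concatenated with `N` spacers, so runtime is linear in
#'   transcriptome size per distinct read length.
#' @export
exact_map <- function(reads, transcripts) {
  stopifnot(inherits(transcripts, "transcriptome"))
  reads <- as.character(reads)
  n <- length(reads)
  seqs <- transcripts$sequences
  spacer <- strrep("N", 40L)
  subject <- Biostrings::DNAString(paste(seqs, collapse = spacer))
  # 0-based offset of each transcript within the concatenated subject
  tx_off <- c(0L, cumsum(nchar(seqs) + 40L))[seq_along(seqs)]
  tx_id <- rep(NA_character_, n)
  fp <- rep(NA_integer_, n)
  nhits <- integer(n)
  uniq <- unique(reads)
  ulen <- nchar(uniq)
  for (w in unique(ulen)) {
    us <- uniq[ulen == w]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(us))
    starts <- Biostrings::startIndex(Biostrings::matchPDict(pd, subject))
    hit_n <- lengths(starts)
    first <- vapply(starts, function(s) if (length(s)) s[[1L]] else NA_integer_,
                    integer(1))
    m <- match(reads, us)           # NA for reads of other lengths
    here <- !is.na(m)
    nhits[here] <- hit_n[m[here]]
    one <- here & nhits == 1L
    s0 <- first[m[one]] - 1L        # 0-based start in concatenated subject
    k <- findInterval(s0, tx_off)
    tx_id[one] <- names(seqs)[k]
    fp[one] <- s0 - tx_off[k]
  }
  keep <- nhits == 1L
  list(
    alignments = data.frame(
      transcript_id = tx_id[keep],
      five_prime = fp[keep],
      length = nchar(reads)[keep],
      stringsAsFactors = FALSE),
    dropped = c(unmapped = sum(nhits == 0L),
                multimapped = sum(nhits > 1L)))
}

#' Footprint length and reading-frame quality control
#'
#' Tallies footprints by length and, within each length, the fraction of
#' 5' ends falling in frames 0/1/2 relative to the annotated CDS. High
#' frame-0 fractions at the dominant footprint lengths indicate stringent
#' nuclease digestion and allow confident A-site assignment.
#'
#' @param alignments data.frame with `transcript_id`, `five_prime`,
#'   `length` (e.g. from [exact_map()] or [read_footprints_bed()]).
#' @param transcripts a [transcriptome].
#' @param lengths integer vector of footprint lengths to report.
#'
#' @return A data.frame of class `qc_summary` with one row per length:
#'   `length`, `n_reads` (all footprints of that length), `n_framed`
#'   (those whose 5' end lies in `[cds_start - 18, cds_end)` and so has a
#'   meaningful frame), and `frac_frame0/1/2` over the framed subset
#'   (NA when `n_framed` is 0).
#'
#' @details Footprints with 5' ends outside the CDS and its 18-nt
#'   upstream extension are excluded from the frame tallies: their frame
#'   relative to the reading frame is not informative.
#' @export
frame_length_qc <- function(alignments, transcripts, lengths = 18:35) {
  stopifnot(inherits(transcripts, "transcriptome"))
  out <- data.frame(length = as.integer(lengths), n_reads = 0L, n_framed = 0L,
                    frac_frame0 = NA_real_, frac_frame1 = NA_real_,
                    frac_frame2 = NA_real_)
  if (nrow(alignments) == 0L) {
    warning("no alignments; returning all-zero QC summary")
    class(out) <- c("qc_summary", "data.frame")
    return(out)
  }
  i <- .tx_index(transcripts, alignments$transcript_id)
  cs <- transcripts$anno$cds_start[i]
  ce <- transcripts$anno$cds_end[i]
  len <- alignments$length
  fp <- alignments$five_prime
  framed <- fp >= cs - 18L & fp < ce
  frame <- (fp - cs) %% 3L
  for (r in seq_len(nrow(out))) {
    this <- len == out$length[r]
    out$n_reads[r] <- sum(this)
    tf <- this & framed
    nf <- sum(tf)
    out$n_framed[r] <- nf
    if (nf > 0L) {
      out$frac_frame0[r] <- sum(frame[tf] == 0L) / nf
      out$frac_frame1[r] <- sum(frame[tf] == 1L) / nf
      out$frac_frame2[r] <- sum(frame[tf] == 2L) / nf
    }
  }
  class(out) <- c("qc_summary", "data.frame")
  out
}
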