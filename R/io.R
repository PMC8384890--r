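#' Read and write footprint alignments as BED6
#'
#' Footprints are stored in transcript coordinates: `chrom` is the
#' transcript id, `start`/`end` the 0-based half-open footprint interval,
#' `score` 1 and `strand` `+`.
#'
#' @param alignments data.frame with `transcript_id`, `five_prime`,
#'   `length`.
#' @param path file path.
#' @return `read_footprints_bed` returns a data.frame with
#'   `transcript_id`, `five_prime`, `length`; `write_footprints_bed`
#'   returns `path` invisibly.
#' @export
write_footprints_bed <- function(alignments, path) {
  n <- nrow(alignments)
  gr <- GenomicRanges::GRanges(
    seqnames = alignments$transcript_id,
    ranges = IRanges::IRanges(start = alignments$five_prime + 1L,
                              width = alignments$length),
    strand = "+")
  gr$name <- sprintf("fp%07d", seq_len(n))
  gr$score <- rep(1L, n)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_footprints_bed
#' @export
read_footprints_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    transcript_id = as.character(GenomicRanges::seqnames(gr)),
    five_prime = GenomicRanges::start(gr) - 1L,
    length = GenomicRanges::width(gr),
    stringsAsFactors = FALSE)
}

#' Read and write reads as FASTQ
#'
#' Thin wrappers around Biostrings' FASTQ support. Synthetic reads carry
#' no meaningful base qualities, so a constant quality (`I`, Phred 40) is
#' written.
#'
#' @param reads named character vector of read sequences.
#' @param path file path.
#' @return `read_fastq` returns a named character vector;
#'   `write_fastq` returns `path` invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(unname(reads))
  names(x) <- if (is.null(names(reads)))
    sprintf("read%07d", seq_along(reads)) else names(reads)
  q <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

# Deterministic TSV writer shared by the pipeline outputs.
.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
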