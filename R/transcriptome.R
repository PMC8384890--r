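#' Build a transcriptome object
#'
#' A `transcriptome` bundles transcript sequences with their CDS
#' annotation. It is the reference against which footprints are mapped,
#' assigned to ribosomal sites, and counted.
#'
#' @param sequences named character vector of nucleotide sequences
#'   (A/C/G/T), one per transcript; names are transcript ids.
#' @param annotation data.frame with columns `transcript_id`, `cds_start`,
#'   `cds_end`. Coordinates are 0-based, half-open: `cds_start` is the
#'   first nucleotide of the start codon, `cds_end` one past the last
#'   nucleotide of the stop codon.
#'
#' @return An object of class `transcriptome`: a list with elements
#'   `sequences` (named character) and `anno` (data.frame with
#'   `transcript_id`, `cds_start`, `cds_end`, `cds_codons`), ordered as in
#'   the annotation.
#'
#' @details The CDS of every transcript must lie within the sequence, have
#'   a length divisible by 3 and span at least 3 codons. Violations are
#'   hard errors naming the offending transcript.
#'
#' @seealso [read_transcriptome()] to construct one from FASTA + TSV files.
#' @export
transcriptome <- function(sequences, annotation) {
  req <- c("transcript_id", "cds_start", "cds_end")
  if (!all(req %in% names(annotation)))
    stop("annotation must have columns: ", paste(req, collapse = ", "))
  ids <- as.character(annotation$transcript_id)
  if (anyDuplicated(ids))
    stop("duplicated transcript_id in annotation: ",
         ids[duplicated(ids)][1L])
  missing_seq <- setdiff(ids, names(sequences))
  if (length(missing_seq))
    stop("transcript_id in annotation but not in FASTA: ", missing_seq[1L])
  sequences <- toupper(sequences[ids])
  cds_start <- as.integer(annotation$cds_start)
  cds_end   <- as.integer(annotation$cds_end)
  len <- nchar(sequences)
  bad <- which(cds_start < 0L | cds_start >= cds_end | cds_end > len)
  if (length(bad))
    stop("CDS out of sequence bounds for transcript ", ids[bad[1L]])
  bad <- which((cds_end - cds_start) %% 3L != 0L)
  if (length(bad))
    stop("CDS not multiple of 3 for transcript ", ids[bad[1L]])
  bad <- which((cds_end - cds_start) %/% 3L < 3L)
  if (length(bad))
    stop("CDS shorter than 3 codons for transcript ", ids[bad[1L]])
  anno <- data.frame(
    transcript_id = ids,
    cds_start = cds_start,
    cds_end = cds_end,
    cds_codons = (cds_end - cds_start) %/% 3L,
    stringsAsFactors = FALSE
  )
  structure(list(sequences = sequences, anno = anno),
            class = "transcriptome")
}

#' Read a transcriptome from FASTA and annotation files
#'
#' @param fasta_path path to a FASTA file of transcript sequences.
#' @param annotation_path path to a tab-separated annotation with header
#'   columns `transcript_id`, `cds_start`, `cds_end` (0-based, half-open).
#'
#' @return A [transcriptome] object, in annotation order.
#'
#' @details Every annotated transcript must be present in the FASTA file;
#'   a missing id is a hard error naming the id. FASTA records without an
#'   annotation row are ignored.
#' @export
read_transcriptome <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  anno <- read.delim(annotation_path, stringsAsFactors = FALSE)
  transcriptome(setNames(as.character(seqs), names(seqs)), anno)
}

#' Write a transcriptome to FASTA and annotation files
#'
#' @param x a [transcriptome].
#' @param fasta_path,annotation_path output paths.
#' @return `x`, invisibly.
#' @export
write_transcriptome <- function(x, fasta_path, annotation_path) {
  stopifnot(inherits(x, "transcriptome"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(x$sequences), fasta_path)
  write.table(x$anno[, c("transcript_id", "cds_start", "cds_end")],
              annotation_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' @export
print.transcriptome <- function(x, ...) {
  cat(sprintf("transcriptome: %d transcripts, CDS %d-%d codons\n",
              nrow(x$anno), min(x$anno$cds_codons), max(x$anno$cds_codons)))
  invisible(x)
}

# --- internal helpers -------------------------------------------------------

# Index of each transcript id in the annotation; errors on unknown ids.
.tx_index <- function(transcripts, transcript_id) {
  i <- match(transcript_id, transcripts$anno$transcript_id)
  if (anyNA(i))
    stop("unknown transcript id: ", transcript_id[which(is.na(i))[1L]])
  i
}

# Flattened codon-position layout over all transcripts: per-transcript
# offsets into one long vector that holds every CDS codon position.
.codon_layout <- function(transcripts) {
  L <- transcripts$anno$cds_codons
  list(L = L, offset = c(0L, cumsum(L))[seq_along(L)], total = sum(L))
}

# Character vector of all CDS codons, flattened in .codon_layout order.
.flat_codons <- function(transcripts) {
  anno <- transcripts$anno
  lay <- .codon_layout(transcripts)
  gidx <- rep.int(seq_len(nrow(anno)), lay$L)
  j <- seq_len(lay$total) - 1L - lay$offset[gidx]   # codon index within gene
  start <- anno$cds_start[gidx] + 3L * j + 1L       # 1-based substr start
  substring(transcripts$sequences[gidx], start, start + 2L)
}

# The 61 sense codons and 3 stop codons (standard genetic code).
.stop_codons <- c("TAA", "TAG", "TGA")

.all_codons <- function() {
  nts <- c("A", "C", "G", "T")
  as.vector(outer(outer(nts, nts, paste0), nts, paste0))
}

.sense_codons <- function() setdiff(sort(.all_codons()), .stop_codons)

# Amino acid for each codon (standard code), via Biostrings.
.codon_aa <- function(codons) {
  as.character(Biostrings::translate(
    Biostrings::DNAStringSet(codons), no.init.codon = TRUE))
}
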