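#' Gene-level footprint counts
#'
#' Counts, per gene, the footprints of one class whose A-site codon lies
#' in `[exclude_first, L_i)`. Excluding the first codons (default 15)
#' keeps initiation-proximal accumulation - inflated by CHX
#' pre-treatment - out of gene-level translation measurements. The
#' result is the per-sample column of a count matrix ready for
#' count-based differential analysis (e.g. DESeq2).
#'
#' @param assignments a `site_assignments` data.frame. For the wide
#'   long-footprint class conventionally used in count matrices
#'   (28-32 nt), run [assign_sites()] with `long_range = c(28, 32)`.
#' @param transcripts a [transcriptome].
#' @param footprint_class `"long"` or `"short"`; any other label is a
#'   hard error.
#' @param exclude_first number of ORF-initial codons excluded.
#'
#' @return Named integer vector of counts, one per gene (annotation
#'   order).
#' @export
gene_counts <- function(assignments, transcripts, footprint_class = "long",
                        exclude_first = 15L) {
  stopifnot(inherits(transcripts, "transcriptome"))
  if (!footprint_class %in% c("long", "short"))
    stop("unknown footprint class: ", footprint_class)
  a <- assignments[assignments$footprint_class == footprint_class, ,
                   drop = FALSE]
  i <- .tx_index(transcripts, a$transcript_id)
  L <- transcripts$anno$cds_codons
  keep <- a$a_site_codon >= exclude_first & a$a_site_codon < L[i]
  n <- tabulate(i[keep], nbins = nrow(transcripts$anno))
  setNames(as.integer(n), transcripts$anno$transcript_id)
}

#' 5'-UTR footprint counts
#'
#' Counts, per gene, the footprints whose A-site codon index is negative,
#' i.e. ribosomes positioned entirely upstream of the annotated start
#' codon. Elevated 5'-UTR counts after CHX pre-treatment flag upstream
#' or alternative initiation.
#'
#' @inheritParams gene_counts
#' @return Named integer vector of counts, one per gene.
#' @export
utr5_counts <- function(assignments, transcripts, footprint_class = "long") {
  stopifnot(inherits(transcripts, "transcriptome"))
  if (!footprint_class %in% c("long", "short"))
    stop("unknown footprint class: ", footprint_class)
  a <- assignments[assignments$footprint_class == footprint_class, ,
                   drop = FALSE]
  i <- .tx_index(transcripts, a$transcript_id)
  n <- tabulate(i[a$a_site_codon < 0L], nbins = nrow(transcripts$anno))
  setNames(as.integer(n), transcripts$anno$transcript_id)
}

#' Assemble a genes x samples count matrix
#'
#' @param assignment_list named list of `site_assignments` data.frames,
#'   one per sample; names become column names.
#' @param transcripts a [transcriptome].
#' @param type `"cds"` (via [gene_counts()]) or `"utr5"` (via
#'   [utr5_counts()]).
#' @param ... passed on to the per-sample counter
#'   (`footprint_class`, `exclude_first`).
#'
#' @return Integer matrix, genes (rows) x samples (columns), with
#'   attributes `footprint_class` and (for `type = "cds"`)
#'   `exclude_first`.
#' @export
count_matrix <- function(assignment_list, transcripts,
                         type = c("cds", "utr5"), ...) {
  type <- match.arg(type)
  if (is.null(names(assignment_list)) ||
      anyDuplicated(names(assignment_list)))
    stop("assignment_list must have unique names (sample ids)")
  counter <- if (type == "cds") gene_counts else utr5_counts
  cols <- lapply(assignment_list, counter, transcripts = transcripts, ...)
  m <- do.call(cbind, cols)
  colnames(m) <- names(assignment_list)
  dots <- list(...)
  attr(m, "footprint_class") <-
    if (!is.null(dots$footprint_class)) dots$footprint_class else "long"
  if (type == "cds")
    attr(m, "exclude_first") <-
      if (!is.null(dots$exclude_first)) dots$exclude_first else 15L
  m
}

#' Write a count matrix as TSV
#'
#' @param m matrix from [count_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(transcript_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}
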