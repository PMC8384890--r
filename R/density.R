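# Internal: per-gene A-site footprint counts over all CDS codon
# positions, flattened in .codon_layout order. Only assignments of the
# requested footprint class with a_site_codon inside [0, L) contribute.
.codon_counts <- function(assignments, transcripts, footprint_class) {
  lay <- .codon_layout(transcripts)
  a <- assignments[assignments$footprint_class == footprint_class, ,
                   drop = FALSE]
  i <- .tx_index(transcripts, a$transcript_id)
  in_cds <- a$a_site_codon >= 0L & a$a_site_codon < lay$L[i]
  pos <- lay$offset[i[in_cds]] + a$a_site_codon[in_cds]   # 0-based flat index
  F <- tabulate(pos + 1L, nbins = lay$total)
  gidx <- rep.int(seq_along(lay$L), lay$L)
  totals <- as.vector(rowsum(F, gidx, reorder = TRUE))
  list(F = F, totals = totals, gidx = gidx, layout = lay)
}

#' Per-gene normalized ribosome density
#'
#' For each gene the A-site footprint count at every CDS codon is
#' normalized by the gene's mean count per codon,
#' `D_ij = F_ij / ((sum_j F_ij) / L_i)`, so that the mean density over
#' each gene's codons is exactly 1. This removes expression differences
#' between genes and makes densities comparable transcriptome-wide.
#'
#' @param assignments a `site_assignments` data.frame from
#'   [assign_sites()].
#' @param transcripts a [transcriptome].
#' @param footprint_class which footprint class to use (`"long"` or
#'   `"short"`); densities are always computed within one class.
#'
#' @return An object of class `gene_density`: a list with
#'   `transcript_id`, `L` (ORF length in codons), `total_reads` (A-site
#'   footprints inside the CDS per gene), `zero_read` (logical flag for
#'   genes with no reads, whose density rows are all zero), and the
#'   flattened per-codon vectors `F` (counts) and `D` (densities), plus
#'   the layout needed to index them. Use [as.data.frame()] for a long
#'   (transcript, codon, count, density) table.
#' @export
gene_density <- function(assignments, transcripts, footprint_class = "long") {
  stopifnot(inherits(transcripts, "transcriptome"))
  cc <- .codon_counts(assignments, transcripts, footprint_class)
  if (any(cc$layout$L == 0L)) stop("gene with zero-length ORF")
  scale <- ifelse(cc$totals > 0, cc$layout$L / cc$totals, 0)
  D <- cc$F * scale[cc$gidx]
  structure(list(
    transcript_id = transcripts$anno$transcript_id,
    L = cc$layout$L,
    total_reads = cc$totals,
    zero_read = cc$totals == 0L,
    F = cc$F, D = D,
    gidx = cc$gidx, offset = cc$layout$offset,
    footprint_class = footprint_class),
    class = "gene_density")
}

#' @export
print.gene_density <- function(x, ...) {
  cat(sprintf(
    "gene_density (%s footprints): %d genes, %d reads in CDS, %d zero-read\n",
    x$footprint_class, length(x$L), sum(x$total_reads), sum(x$zero_read)))
  invisible(x)
}

#' @export
as.data.frame.gene_density <- function(x, ...) {
  data.frame(
    transcript_id = rep.int(x$transcript_id, x$L),
    codon = unlist(lapply(x$L, seq_len), use.names = FALSE) - 1L,
    count = x$F,
    density = x$D,
    stringsAsFactors = FALSE)
}

# Internal: density vector of a single gene by id.
.density_of <- function(gd, transcript_id) {
  i <- match(transcript_id, gd$transcript_id)
  if (is.na(i)) stop("unknown transcript id: ", transcript_id)
  gd$D[gd$offset[i] + seq_len(gd$L[i])]
}
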