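#' Transcriptome-wide codon occupancy at a ribosomal site
#'
#' Codon occupancy measures the average normalized ribosome density
#' observed when a given codon sits in a given ribosomal site: a proxy
#' for relative dwell (decoding) time. Per well-expressed gene, A-site
#' footprint counts over the retained codon positions are normalized to
#' a mean of 1 (as in [gene_density()], but over the retained positions
#' only); the occupancy of codon `c` is then the mean normalized density
#' over all retained positions, in all passing genes, whose codon at the
#' requested site is `c`.
#'
#' @param assignments a `site_assignments` data.frame.
#' @param transcripts a [transcriptome].
#' @param site `"A"`, `"P"` or `"E"`. Density is always recorded at the
#'   A-site codon position; for the P and E sites the codon identity is
#'   looked up one and two codons upstream (the codons those sites hold
#'   when the A-site is at the recorded position).
#' @param min_reads well-expressed gene cutoff (strictly greater than).
#' @param exclude_first,exclude_last codons trimmed from each ORF's
#'   start and end before normalization and averaging, shielding the
#'   statistic from initiation/termination accumulation (defaults 15
#'   and 5).
#' @param footprint_class footprint class analyzed.
#'
#' @return A data.frame of class `codon_occupancy` with one row per
#'   codon (all 64): `codon`, `amino_acid`, `site`, `footprint_class`,
#'   `occupancy` (NA when no position contributed), `n_positions`,
#'   `n_reads`. The position-weighted mean occupancy over contributing
#'   codons is 1 by construction.
#' @export
codon_occupancy <- function(assignments, transcripts, site = c("A", "P", "E"),
                            min_reads = 64L, exclude_first = 15L,
                            exclude_last = 5L, footprint_class = "long") {
  site <- match.arg(site)
  stopifnot(inherits(transcripts, "transcriptome"))
  shift <- c(A = 0L, P = 1L, E = 2L)[[site]]
  cc <- .codon_counts(assignments, transcripts, footprint_class)
  lay <- cc$layout
  j <- seq_len(lay$total) - 1L - lay$offset[cc$gidx]
  Lpos <- lay$L[cc$gidx]
  retained <- j >= exclude_first & j < Lpos - exclude_last
  gene_pass <- cc$totals > min_reads
  use <- retained & gene_pass[cc$gidx]
  # renormalize per gene over the retained positions
  n_ret <- as.vector(rowsum(as.integer(use), cc$gidx, reorder = TRUE))
  reads_ret <- as.vector(rowsum(cc$F * use, cc$gidx, reorder = TRUE))
  ok <- gene_pass & reads_ret > 0
  use <- use & ok[cc$gidx]
  D <- numeric(lay$total)
  D[use] <- cc$F[use] * (n_ret / reads_ret)[cc$gidx[use]]
  # codon identity at the requested site: shift the lookup upstream,
  # staying within the same gene's CDS
  site_j <- j - shift
  use <- use & site_j >= 0L
  codons <- .flat_codons(transcripts)
  site_codon <- codons[which(use) - shift]
  all64 <- sort(.all_codons())
  f <- factor(site_codon, levels = all64)
  occ <- tapply(D[use], f, mean)
  npos <- tabulate(f, nbins = 64L)
  nreads <- tapply(cc$F[use], f, sum)
  out <- data.frame(
    codon = all64,
    amino_acid = .codon_aa(all64),
    site = site,
    footprint_class = footprint_class,
    occupancy = as.numeric(occ),
    n_positions = npos,
    n_reads = as.integer(ifelse(is.na(nreads), 0L, nreads)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_genes") <- sum(ok)
  class(out) <- c("codon_occupancy", "data.frame")
  out
}

#' Compare codon occupancy between two conditions
#'
#' Pearson correlation of per-codon occupancy values between two tables
#' (e.g. two drug-treatment regimens), summarized as a signed
#' R-squared, `sign(r) * r^2`, so that anti-correlated occupancy
#' profiles yield negative values. Comparisons whose correlation is not
#' significant at p = 0.05 are flagged (`crossed_out`).
#'
#' @param table_x,table_y `codon_occupancy` tables from the same
#'   ribosomal site.
#' @param use_stops include the three stop codons (default FALSE:
#'   termination occupancy reflects a distinct process and is excluded
#'   from cross-condition comparisons).
#'
#' @return A list of class `occupancy_comparison`: `signed_R2`, `r`,
#'   `p_value`, `n` (codons used), `crossed_out` (p > 0.05), and `data`
#'   (codon, x, y).
#'
#' @details Codons with missing occupancy in either table are dropped
#'   pairwise; fewer than 4 shared codons is a hard error.
#' @export
compare_occupancy <- function(table_x, table_y, use_stops = FALSE) {
  stopifnot(inherits(table_x, "codon_occupancy"),
            inherits(table_y, "codon_occupancy"))
  if (table_x$site[1L] != table_y$site[1L])
    stop("tables are from different ribosomal sites: ",
         table_x$site[1L], " vs ", table_y$site[1L])
  m <- merge(table_x[, c("codon", "occupancy")],
             table_y[, c("codon", "occupancy")],
             by = "codon", suffixes = c("_x", "_y"))
  if (!use_stops) m <- m[!m$codon %in% .stop_codons, , drop = FALSE]
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 4L)
    stop("fewer than 4 shared codons with occupancy values")
  ct <- cor.test(m$occupancy_x, m$occupancy_y, method = "pearson")
  r <- unname(ct$estimate)
  structure(list(
    signed_R2 = sign(r) * r^2,
    r = r,
    p_value = ct$p.value,
    n = nrow(m),
    crossed_out = ct$p.value > 0.05,
    data = data.frame(codon = m$codon, x = m$occupancy_x, y = m$occupancy_y,
                      stringsAsFactors = FALSE)),
    class = "occupancy_comparison")
}

#' @export
print.occupancy_comparison <- function(x, ...) {
  cat(sprintf("occupancy comparison: signed R2 = %.3f (r = %.3f, p = %.3g, n = %d)%s\n",
              x$signed_R2, x$r, x$p_value, x$n,
              if (x$crossed_out) " [not significant]" else ""))
  invisible(x)
}
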