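#' Metagene profile of normalized ribosome density
#'
#' Averages per-gene normalized densities ([gene_density()]) across
#' well-expressed genes at aligned codon offsets,
#' `A_j = (sum_i D_ij) / N`, anchored either at the start codon (the
#' first `window` codons) or at the stop codon (the last `window`
#' codons). The start-anchored profile visualizes the 5' translation
#' ramp; the stop-anchored profile shows terminal accumulation.
#'
#' @param assignments a `site_assignments` data.frame.
#' @param transcripts a [transcriptome].
#' @param anchor `"start"` or `"stop"`.
#' @param window number of codon offsets to report.
#' @param min_reads genes must have more than this many A-site-assigned
#'   footprints in the CDS (default `> 64`, the well-expressed cutoff).
#' @param min_len genes must have an ORF of at least this many codons
#'   (default 200), so every gene contributes to every offset.
#' @param footprint_class footprint class analyzed.
#'
#' @return A data.frame of class `metagene_profile` with columns
#'   `anchor`, `offset` (1-based: offset 1 is the first codon of the
#'   window), `A` (mean density), `ci_lo`, `ci_hi` (95% normal-theory
#'   confidence band across genes) and `N` (number of contributing
#'   genes).
#'
#' @details Genes shorter than `max(min_len, window)` codons are
#'   excluded. If no gene passes, the filters are named in the error.
#' @export
metagene_profile <- function(assignments, transcripts,
                             anchor = c("start", "stop"), window = 200L,
                             min_reads = 64L, min_len = 200L,
                             footprint_class = "long") {
  anchor <- match.arg(anchor)
  gd <- gene_density(assignments, transcripts, footprint_class)
  pass <- gd$total_reads > min_reads & gd$L >= max(min_len, window)
  N <- sum(pass)
  if (N == 0L)
    stop(sprintf(
      "no genes pass the filters (> %d reads and >= %d codons)",
      min_reads, max(min_len, window)))
  off <- gd$offset[pass]
  L <- gd$L[pass]
  first <- if (anchor == "start") off else off + (L - window)
  idx <- outer(first, seq_len(window) - 1L, `+`) + 1L   # N x window
  M <- matrix(gd$D[idx], nrow = N)
  A <- colMeans(M)
  se <- apply(M, 2L, sd) / sqrt(N)
  out <- data.frame(anchor = anchor, offset = seq_len(window),
                    A = A, ci_lo = A - qnorm(0.975) * se,
                    ci_hi = A + qnorm(0.975) * se, N = N)
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' Codon-anchored downstream enrichment ("wave") profile
#'
#' For every occurrence of a query codon in well-expressed genes, the
#' per-gene normalized density is collected at each relative codon
#' offset `d` and averaged over occurrences. Excess density at positive
#' offsets downstream of a codon - a "wave" - is the signature of
#' ribosomes that continued elongating after drug treatment until
#' stalling behind a slowly decoded codon, as reported for CGA/CGG in
#' CHX-pretreated budding yeast.
#'
#' @param assignments a `site_assignments` data.frame.
#' @param transcripts a [transcriptome].
#' @param query_codon a sense codon, e.g. `"CGA"` (DNA alphabet).
#' @param d_min,d_max codon-offset window relative to the occurrence
#'   (negative = upstream).
#' @param min_reads well-expressed gene cutoff (strictly greater).
#' @param exclude_edges occurrences within this many codons of the start
#'   or stop are skipped, keeping the profile clear of initiation and
#'   termination accumulation.
#' @param footprint_class footprint class analyzed.
#'
#' @return A data.frame of class `wave_profile` with columns `codon`,
#'   `d`, `enrichment` (mean density over occurrences; 1 = gene
#'   average), `n` (occurrence-positions averaged at that offset), and
#'   attribute `n_occurrences` (query-codon occurrences used).
#'
#' @details Offsets falling outside the CDS of a given occurrence's gene
#'   are simply not collected for that occurrence. Overlapping
#'   occurrences are used independently. Zero usable occurrences is a
#'   hard error.
#' @export
wave_profile <- function(assignments, transcripts, query_codon,
                         d_min = -20L, d_max = 100L, min_reads = 64L,
                         exclude_edges = 20L, footprint_class = "long") {
  query_codon <- toupper(query_codon)
  if (!query_codon %in% .sense_codons())
    stop("query_codon must be one of the 61 sense codons, got ", query_codon)
  gd <- gene_density(assignments, transcripts, footprint_class)
  codons <- .flat_codons(transcripts)
  .wave_from_density(gd, codons, query_codon, d_min, d_max, min_reads,
                     exclude_edges)
}

#' Wave profiles for many query codons at once
#'
#' Computes [wave_profile()] for each codon in `query_codons`, reusing
#' one density computation and codon grid, which is substantially faster
#' than repeated single-codon calls when scanning all 61 sense codons.
#'
#' @inheritParams wave_profile
#' @param query_codons character vector of sense codons (default: all 61).
#' @return A data.frame of class `wave_profile` stacking the per-codon
#'   profiles (columns `codon`, `d`, `enrichment`, `n`).
#' @export
wave_profiles <- function(assignments, transcripts,
                          query_codons = .sense_codons(),
                          d_min = -20L, d_max = 100L, min_reads = 64L,
                          exclude_edges = 20L, footprint_class = "long") {
  gd <- gene_density(assignments, transcripts, footprint_class)
  codons <- .flat_codons(transcripts)
  out <- do.call(rbind, lapply(query_codons, function(cdn)
    .wave_from_density(gd, codons, cdn, d_min, d_max, min_reads,
                       exclude_edges)))
  class(out) <- c("wave_profile", "data.frame")
  out
}

# Core wave computation, reusable across codons without recomputing the
# density or the codon grid.
.wave_from_density <- function(gd, codons, query_codon, d_min, d_max,
                               min_reads, exclude_edges) {
  pass <- gd$total_reads > min_reads
  pos_pass <- pass[gd$gidx]
  j <- seq_along(gd$D) - 1L - gd$offset[gd$gidx]   # codon index within gene
  Lpos <- gd$L[gd$gidx]
  interior <- j >= exclude_edges & j < Lpos - exclude_edges
  occ <- which(pos_pass & interior & codons == query_codon)
  if (length(occ) == 0L)
    stop("no usable occurrences of ", query_codon,
         " in genes passing the read filter")
  docs <- seq.int(d_min, d_max)
  occ_j <- j[occ]
  occ_L <- Lpos[occ]
  # occurrences x offsets matrices of flat positions and validity
  tgt <- outer(occ, docs, `+`)
  valid <- outer(occ_j, docs, `+`) >= 0L & outer(occ_j, docs, `+`) < occ_L
  vals <- matrix(gd$D[tgt], nrow = length(occ))
  vals[!valid] <- NA_real_
  out <- data.frame(
    codon = query_codon, d = docs,
    enrichment = colMeans(vals, na.rm = TRUE),
    n = colSums(valid))
  attr(out, "n_occurrences") <- length(occ)
  class(out) <- c("wave_profile", "data.frame")
  out
}
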