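#' Configuration of the synthetic footprint generator
#'
#' Collects every parameter of the generative model behind
#' [simulate_transcriptome()] and [simulate_footprints()]. The model
#' emulates the statistical structure of ribosome profiling libraries:
#' a per-codon dwell intensity
#' `lambda_ij = w_c(i,j) * r(j) * s_start(j) * s_stop(j) * wave(i,j)`
#' (codon dwell weight, 5' ramp, start/stop accumulation, multiplicative
#' downstream waves behind target codons), gene totals proportional to
#' expression times summed intensity, multinomial A-site sampling, and
#' per-read emission of footprint class, length and 5'-end frame.
#'
#' @param seed integer seed; identical configurations (including the
#'   seed) produce byte-identical outputs.
#' @param n_genes number of transcripts.
#' @param orf_length inclusive range of ORF lengths (codons), sampled
#'   uniformly.
#' @param utr5_length,utr3_length UTR lengths (nt).
#' @param expression_meanlog,expression_sdlog log-normal gene expression
#'   parameters.
#' @param total_footprints total reads emitted.
#' @param dwell_weights named numeric vector of dwell weights over the
#'   61 sense codons, or NULL.
#' @param dwell_sdlog if `dwell_weights` is NULL and this is > 0, weights
#'   are drawn log-normally with this sdlog (meanlog 0); 0 means flat.
#' @param ramp_amplitude,ramp_tau 5' ramp `r(j) = 1 + a * exp(-j / tau)`
#'   over codon index j; amplitude 0 disables the ramp.
#' @param start_boost multiplier on codons 0-2 (initiation accumulation).
#' @param stop_boost multiplier on the last codon (termination
#'   accumulation).
#' @param wave_codons character vector of target codons behind which a
#'   downstream wave is injected (empty: no waves).
#' @param wave_amplitude,wave_tau,wave_extent wave kernel
#'   `1 + alpha * exp(-d / tau)` applied at 1 <= d <= extent codons
#'   downstream of each target-codon occurrence, multiplicatively across
#'   occurrences.
#' @param p_long probability a read is a long footprint.
#' @param long_lengths,long_probs,short_lengths,short_probs footprint
#'   length distributions within each class.
#' @param frame_probs probabilities of emitting the 5' end in frame 0,
#'   -1, +1 (in that order).
#' @param utr5_mass fraction of each gene's read mass placed on the
#'   5'-UTR A-site positions -6..-1 (the 18-nt mapping extension).
#' @param adapter constant 3' adapter appended (after 4 random linker
#'   nucleotides) when emitting FASTQ.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_genes = 500L,
                       orf_length = c(200L, 600L),
                       utr5_length = 60L,
                       utr3_length = 60L,
                       expression_meanlog = 0,
                       expression_sdlog = 0.5,
                       total_footprints = 2.5e6,
                       dwell_weights = NULL,
                       dwell_sdlog = 0,
                       ramp_amplitude = 0,
                       ramp_tau = 50,
                       start_boost = 1,
                       stop_boost = 1,
                       wave_codons = character(0),
                       wave_amplitude = 0.5,
                       wave_tau = 10,
                       wave_extent = 60L,
                       p_long = 0.8,
                       long_lengths = 29:31,
                       long_probs = c(0.25, 0.5, 0.25),
                       short_lengths = 21:22,
                       short_probs = c(0.5, 0.5),
                       frame_probs = c(0.87, 0.10, 0.03),
                       utr5_mass = 0.01,
                       adapter = "AGATCGGAAGAGC") {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              orf_length = as.integer(orf_length),
              utr5_length = as.integer(utr5_length),
              utr3_length = as.integer(utr3_length),
              expression_meanlog = expression_meanlog,
              expression_sdlog = expression_sdlog,
              total_footprints = as.integer(total_footprints),
              dwell_weights = dwell_weights, dwell_sdlog = dwell_sdlog,
              ramp_amplitude = ramp_amplitude, ramp_tau = ramp_tau,
              start_boost = start_boost, stop_boost = stop_boost,
              wave_codons = toupper(wave_codons),
              wave_amplitude = wave_amplitude, wave_tau = wave_tau,
              wave_extent = as.integer(wave_extent),
              p_long = p_long,
              long_lengths = as.integer(long_lengths),
              long_probs = long_probs,
              short_lengths = as.integer(short_lengths),
              short_probs = short_probs,
              frame_probs = frame_probs,
              utr5_mass = utr5_mass,
              adapter = adapter)
  stopifnot(cfg$n_genes >= 1L,
            length(cfg$orf_length) == 2L,
            cfg$orf_length[1L] <= cfg$orf_length[2L],
            cfg$utr5_length >= 0L, cfg$utr3_length >= 0L,
            cfg$total_footprints >= 1L,
            cfg$dwell_sdlog >= 0, cfg$ramp_tau > 0,
            cfg$start_boost > 0, cfg$stop_boost > 0,
            cfg$wave_amplitude >= 0, cfg$wave_tau > 0, cfg$wave_extent >= 1L,
            cfg$p_long >= 0, cfg$p_long <= 1,
            length(cfg$long_probs) == length(cfg$long_lengths),
            length(cfg$short_probs) == length(cfg$short_lengths),
            all(cfg$long_probs >= 0), all(cfg$short_probs >= 0),
            length(cfg$frame_probs) == 3L, all(cfg$frame_probs >= 0),
            abs(sum(cfg$frame_probs) - 1) < 1e-9,
            cfg$utr5_mass >= 0, cfg$utr5_mass < 1)
  if (cfg$orf_length[1L] < 10L)
    stop("minimum ORF length is 10 codons")
  if (!is.null(cfg$dwell_weights)) {
    if (!all(.sense_codons() %in% names(cfg$dwell_weights)))
      stop("dwell_weights must be named for all 61 sense codons")
    if (any(cfg$dwell_weights <= 0)) stop("dwell weights must be > 0")
  }
  if (length(cfg$wave_codons) &&
      !all(cfg$wave_codons %in% .sense_codons()))
    stop("wave_codons must be sense codons")
  structure(cfg, class = "sim_config")
}

#' Simulate a transcriptome
#'
#' Generates random transcripts: a 5' UTR, an ORF starting with ATG,
#' internal codons drawn uniformly from the 61 sense codons (so no
#' premature in-frame stop can occur), a single stop codon, and a 3'
#' UTR. ORF lengths are uniform over `config$orf_length`.
#'
#' @param config a [sim_config()].
#' @return A [transcriptome] with `config$n_genes` transcripts named
#'   `g0001`, `g0002`, ...
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  L <- sample.int(config$orf_length[2L] - config$orf_length[1L] + 1L,
                  n, replace = TRUE) + config$orf_length[1L] - 1L
  nts <- c("A", "C", "G", "T")
  sense <- .sense_codons()
  rand_nt <- function(total) sample(nts, total, replace = TRUE)
  utr5 <- vapply(seq_len(n), function(i)
    paste(rand_nt(config$utr5_length), collapse = ""), character(1))
  utr3 <- vapply(seq_len(n), function(i)
    paste(rand_nt(config$utr3_length), collapse = ""), character(1))
  n_internal <- L - 2L
  internal <- sample(sense, sum(n_internal), replace = TRUE)
  stops <- sample(.stop_codons, n, replace = TRUE)
  grp <- rep.int(seq_len(n), n_internal)
  body <- vapply(split(internal, grp), paste, character(1), collapse = "")
  seqs <- paste0(utr5, "ATG", body, stops, utr3)
  ids <- sprintf("g%04d", seq_len(n))
  transcriptome(setNames(seqs, ids),
                data.frame(transcript_id = ids,
                           cds_start = config$utr5_length,
                           cds_end = config$utr5_length + 3L * L))
}

# Internal: per-position dwell intensity lambda over all CDS codons
# (flattened), together with the dwell weights actually used.
.dwell_intensity <- function(transcripts, config, dwell_weights) {
  lay <- .codon_layout(transcripts)
  gidx <- rep.int(seq_along(lay$L), lay$L)
  j <- seq_len(lay$total) - 1L - lay$offset[gidx]
  Lpos <- lay$L[gidx]
  codons <- .flat_codons(transcripts)
  w_all <- setNames(rep(1, 64L), sort(.all_codons()))
  w_all[names(dwell_weights)] <- dwell_weights
  lambda <- unname(w_all[codons])
  if (config$ramp_amplitude != 0)
    lambda <- lambda * (1 + config$ramp_amplitude * exp(-j / config$ramp_tau))
  if (config$start_boost != 1)
    lambda[j <= 2L] <- lambda[j <= 2L] * config$start_boost
  if (config$stop_boost != 1)
    lambda[j == Lpos - 1L] <- lambda[j == Lpos - 1L] * config$stop_boost
  if (length(config$wave_codons) && config$wave_amplitude > 0) {
    kern <- log1p(config$wave_amplitude *
                    exp(-seq_len(config$wave_extent) / config$wave_tau))
    logf <- numeric(lay$total)
    occ <- which(codons %in% config$wave_codons)
    occ_g <- gidx[occ]
    gene_end <- lay$offset + lay$L          # one past last flat index, 0-based
    for (k in seq_along(occ)) {
      p <- occ[k]                           # 1-based flat position
      lim <- min(config$wave_extent, gene_end[occ_g[k]] - p)
      if (lim >= 1L) {
        rng <- p + seq_len(lim)
        logf[rng] <- logf[rng] + kern[seq_len(lim)]
      }
    }
    lambda <- lambda * exp(logf)
  }
  list(lambda = lambda, layout = lay, gidx = gidx, j = j)
}

#' Simulate a footprint library with known ground truth
#'
#' Draws A-site positions from the per-codon dwell intensities defined
#' by `config` (see [sim_config()]), then emits each read's footprint
#' class, length and 5'-end frame, computing the 5' coordinate by
#' inverting the site-assignment offsets (frame 0: codon start - 15;
#' frame -1: codon start - 16; frame +1: codon start - 14). A fraction
#' `utr5_mass` of each gene's reads is placed on 5'-UTR A-site positions
#' -6..-1.
#'
#' @param transcripts a [transcriptome] from [simulate_transcriptome()].
#' @param config the same [sim_config()].
#'
#' @return A list of class `ribosim`:
#' \describe{
#'   \item{alignments}{data.frame `transcript_id`, `five_prime`,
#'     `length` - the simulated library.}
#'   \item{truth_reads}{per-read ground truth aligned with `alignments`:
#'     true A-site codon, footprint class, emitted frame.}
#'   \item{expected_density}{per-(gene, codon) expected normalized
#'     density (the dwell intensity pushed through the per-gene
#'     normalization analytically).}
#'   \item{dwell_weights}{the 61 sense-codon dwell weights used.}
#'   \item{n_resampled, n_dropped}{reads whose emission geometry fell
#'     outside the transcript and were redrawn / finally discarded.}
#' }
#'
#' @details Reads are emitted deterministically given the configuration:
#'   the generator seeds R's RNG from `config$seed` (offset so that the
#'   transcriptome and library draws use distinct streams).
#' @export
simulate_footprints <- function(transcripts, config) {
  stopifnot(inherits(transcripts, "transcriptome"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n_genes <- nrow(transcripts$anno)
  dw <- config$dwell_weights
  if (is.null(dw)) {
    dw <- setNames(rep(1, 61L), .sense_codons())
    if (config$dwell_sdlog > 0)
      dw <- setNames(rlnorm(61L, 0, config$dwell_sdlog), .sense_codons())
  }
  di <- .dwell_intensity(transcripts, config, dw)
  lay <- di$layout
  gene_sum <- as.vector(rowsum(di$lambda, di$gidx, reorder = TRUE))
  expression <- rlnorm(n_genes, config$expression_meanlog,
                       config$expression_sdlog)
  m <- config$utr5_mass
  # probability mass: CDS positions, then 6 UTR positions per gene.
  # Gene totals are proportional to expression * sum(lambda); the UTR
  # receives fraction m of each gene's mass, spread over 6 positions.
  p_cds <- expression[di$gidx] * di$lambda
  utr_per_pos <- expression * gene_sum * m / ((1 - m) * 6)
  prob <- c(p_cds, rep(utr_per_pos, each = 6L))
  counts <- rmultinom(1L, config$total_footprints, prob)[, 1L]
  cell <- rep.int(seq_along(counts), counts)
  is_utr <- cell > lay$total
  g <- integer(length(cell))
  a <- integer(length(cell))
  g[!is_utr] <- di$gidx[cell[!is_utr]]
  a[!is_utr] <- di$j[cell[!is_utr]]
  uc <- cell[is_utr] - lay$total - 1L           # 0-based UTR cell
  g[is_utr] <- uc %/% 6L + 1L
  a[is_utr] <- uc %% 6L - 6L                    # A-site codons -6..-1
  n <- length(cell)
  cs <- transcripts$anno$cds_start[g]
  tx_len <- nchar(transcripts$sequences)[g]
  draw_emission <- function(k) {
    long <- runif(k) < config$p_long
    len <- integer(k)
    len[long] <- config$long_lengths[
      sample.int(length(config$long_lengths), sum(long), replace = TRUE,
                 prob = config$long_probs)]
    len[!long] <- config$short_lengths[
      sample.int(length(config$short_lengths), sum(!long), replace = TRUE,
                 prob = config$short_probs)]
    fr <- sample.int(3L, k, replace = TRUE, prob = config$frame_probs)
    list(long = long, len = len, frame = fr)
  }
  offsets <- c(-15L, -16L, -14L)                # frame 0, -1, +1
  em <- draw_emission(n)
  fp <- cs + 3L * a + offsets[em$frame]
  bad <- fp < 0L | fp + em$len > tx_len
  n_resampled <- 0L
  iter <- 0L
  while (any(bad) && iter < 20L) {
    iter <- iter + 1L
    n_resampled <- n_resampled + sum(bad)
    redo <- draw_emission(sum(bad))
    em$long[bad] <- redo$long
    em$len[bad] <- redo$len
    em$frame[bad] <- redo$frame
    fp[bad] <- cs[bad] + 3L * a[bad] + offsets[redo$frame]
    bad <- fp < 0L | fp + em$len > tx_len
  }
  keep <- !bad
  ids <- transcripts$anno$transcript_id
  frame_label <- c(0L, -1L, 1L)
  alignments <- data.frame(
    transcript_id = ids[g[keep]],
    five_prime = fp[keep],
    length = em$len[keep],
    stringsAsFactors = FALSE)
  truth_reads <- data.frame(
    transcript_id = ids[g[keep]],
    a_site_codon = a[keep],
    footprint_class = ifelse(em$long[keep], "long", "short"),
    frame = frame_label[em$frame[keep]],
    stringsAsFactors = FALSE)
  expected_density <- data.frame(
    transcript_id = rep.int(ids, lay$L),
    codon = di$j,
    density = di$lambda * (lay$L / gene_sum)[di$gidx],
    stringsAsFactors = FALSE)
  structure(list(
    alignments = alignments,
    truth_reads = truth_reads,
    expected_density = expected_density,
    dwell_weights = dw,
    n_resampled = n_resampled,
    n_dropped = sum(bad),
    config = config),
    class = "ribosim")
}

#' @export
print.ribosim <- function(x, ...) {
  cat(sprintf(
    "ribosim: %d reads over %d genes (%d resampled, %d dropped)\n",
    nrow(x$alignments), x$config$n_genes, x$n_resampled, x$n_dropped))
  invisible(x)
}

#' Emit raw synthetic reads as FASTQ
#'
#' Converts simulated footprints into raw reads as they would leave the
#' sequencer: the footprint sequence followed by a 4-nt randomized
#' linker and the constant 3' adapter, ready for [clip_and_trim()] and
#' [exact_map()].
#'
#' @param sim a `ribosim` from [simulate_footprints()].
#' @param transcripts the matching [transcriptome].
#' @param path optional FASTQ output path; if NULL, reads are only
#'   returned.
#' @return Named character vector of raw reads (invisibly if `path` is
#'   given).
#' @export
sim_fastq <- function(sim, transcripts, path = NULL) {
  stopifnot(inherits(sim, "ribosim"), inherits(transcripts, "transcriptome"))
  set.seed(sim$config$seed + 2L)
  al <- sim$alignments
  seqs <- transcripts$sequences[al$transcript_id]
  insert <- substring(seqs, al$five_prime + 1L, al$five_prime + al$length)
  nts <- c("A", "C", "G", "T")
  linker <- matrix(sample(nts, 4L * nrow(al), replace = TRUE), ncol = 4L)
  linker <- paste0(linker[, 1L], linker[, 2L], linker[, 3L], linker[, 4L])
  reads <- setNames(paste0(insert, linker, sim$config$adapter),
                    sprintf("read%07d", seq_len(nrow(al))))
  if (!is.null(path)) {
    write_fastq(reads, path)
    return(invisible(reads))
  }
  reads
}
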