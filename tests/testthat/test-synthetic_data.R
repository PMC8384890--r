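test_that("simulated transcriptomes have well-formed ORFs", {
  cfg <- sim_config(seed = 1, n_genes = 50, orf_length = c(60, 120),
                    total_footprints = 100)
  tx <- simulate_transcriptome(cfg)
  expect_equal(nrow(tx$anno), 50L)
  starts <- substring(tx$sequences, tx$anno$cds_start + 1,
                      tx$anno$cds_start + 3)
  expect_true(all(starts == "ATG"))
  stops <- substring(tx$sequences, tx$anno$cds_end - 2, tx$anno$cds_end)
  expect_true(all(stops %in% c("TAA", "TAG", "TGA")))
  # no premature in-frame stop in any CDS
  for (i in seq_len(50)) {
    cds <- substring(tx$sequences[i], tx$anno$cds_start[i] + 1,
                     tx$anno$cds_end[i])
    cods <- substring(cds, seq(1, nchar(cds) - 3, 3),
                      seq(3, nchar(cds) - 1, 3))
    internal <- cods[-length(cods)]
    expect_false(any(internal %in% c("TAA", "TAG", "TGA")))
  }
  expect_error(sim_config(seed = 1, orf_length = c(5, 20)),
               "minimum ORF length")
})

test_that("the generator is deterministic given the configuration", {
  cfg <- sim_config(seed = 9, n_genes = 20, orf_length = c(80, 160),
                    total_footprints = 2e4, wave_codons = "CGA",
                    dwell_sdlog = 0.2)
  tx1 <- simulate_transcriptome(cfg)
  tx2 <- simulate_transcriptome(cfg)
  expect_identical(tx1$sequences, tx2$sequences)
  s1 <- simulate_footprints(tx1, cfg)
  s2 <- simulate_footprints(tx2, cfg)
  expect_identical(s1$alignments, s2$alignments)
  expect_identical(s1$truth_reads, s2$truth_reads)
  expect_identical(s1$dwell_weights, s2$dwell_weights)
  expect_identical(sim_fastq(s1, tx1), sim_fastq(s2, tx2))
})

test_that("emitted read count equals the configured total minus drops", {
  cfg <- sim_config(seed = 10, n_genes = 20, orf_length = c(80, 160),
                    total_footprints = 2e4)
  tx <- simulate_transcriptome(cfg)
  sim <- simulate_footprints(tx, cfg)
  expect_equal(nrow(sim$alignments) + sim$n_dropped, 2e4)
  expect_equal(nrow(sim$truth_reads), nrow(sim$alignments))
})

test_that("frame emission probabilities are honoured", {
  cfg <- sim_config(seed = 11, n_genes = 50, orf_length = c(150, 250),
                    total_footprints = 5e4,
                    frame_probs = c(0.7, 0.2, 0.1))
  tx <- simulate_transcriptome(cfg)
  sim <- simulate_footprints(tx, cfg)
  frac <- prop.table(table(sim$truth_reads$frame))
  se <- sqrt(0.7 * 0.3 / 5e4)
  expect_lt(abs(frac[["0"]] - 0.7), 4 * se)
  expect_lt(abs(frac[["-1"]] - 0.2), 4 * sqrt(0.2 * 0.8 / 5e4))
})

test_that("expected densities pushed through the estimator match the truth", {
  cfg <- sim_config(seed = 12, n_genes = 80, orf_length = c(200, 280),
                    total_footprints = 1e6, expression_sdlog = 0,
                    ramp_amplitude = 1, ramp_tau = 50)
  tx <- simulate_transcriptome(cfg)
  sim <- simulate_footprints(tx, cfg)
  asn <- assign_sites(sim$alignments, tx)
  mp <- metagene_profile(asn, tx, "start", window = 150, min_len = 150)
  gd <- gene_density(asn, tx)
  pass <- gd$transcript_id[gd$total_reads > 64 & gd$L >= 200]
  ed <- sim$expected_density
  ed <- ed[ed$transcript_id %in% pass & ed$codon < 150, ]
  predicted <- as.numeric(tapply(ed$density, ed$codon, mean))
  expect_lt(max(abs(mp$A - predicted)), 0.12)
  expect_gt(cor(mp$A, predicted), 0.95)
})

test_that("raw FASTQ emission is invertible by clip_and_trim + exact_map", {
  cfg <- sim_config(seed = 16, n_genes = 15, orf_length = c(80, 160),
                    total_footprints = 2000)
  tx <- simulate_transcriptome(cfg)
  sim <- simulate_footprints(tx, cfg)
  raw <- sim_fastq(sim, tx)
  clipped <- clip_and_trim(raw, cfg$adapter)
  # adapter-bearing reads whose insert is clean recover the footprint
  expect_gt(length(clipped$reads), 0.95 * length(raw))
  k <- match(names(clipped$reads), names(raw))
  truth <- substring(tx$sequences[sim$alignments$transcript_id[k]],
                     sim$alignments$five_prime[k] + 1,
                     sim$alignments$five_prime[k] + sim$alignments$length[k])
  expect_equal(unname(clipped$reads), unname(truth))
  mapped <- exact_map(clipped$reads, tx)
  expect_equal(nrow(mapped$alignments) + sum(mapped$dropped),
               length(clipped$reads))
})
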