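test_that("gene_density implements per-gene mean-1 normalization", {
  tx <- toy_transcriptome(list(c("ATG", "GCT", "GAA", "TAA"),
                               c("ATG", "GCT", "TAA")))
  asn <- fake_assignments(
    rep(c("t01", "t02"), c(8, 9)),
    c(rep(0, 2), rep(2, 4), rep(3, 2),     # F = [2,0,4,2]
      rep(0:2, each = 3)))                 # F = [3,3,3]
  gd <- gene_density(asn, tx)
  expect_equal(gd$D[1:4], c(1, 0, 2, 1))
  expect_equal(gd$D[5:7], c(1, 1, 1))
  df <- as.data.frame(gd)
  expect_equal(tapply(df$density, df$transcript_id, mean),
               c(t01 = 1, t02 = 1), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zero-read genes yield all-zero density and are flagged", {
  tx <- toy_transcriptome(list(c("ATG", "GCT", "GAA", "TAA"),
                               c("ATG", "GCT", "TAA")))
  asn <- fake_assignments("t01", c(0, 1, 2, 3))
  gd <- gene_density(asn, tx)
  expect_equal(gd$zero_read, c(FALSE, TRUE))
  expect_true(all(gd$D[5:7] == 0))
})

test_that("metagene_profile averages aligned densities over passing genes", {
  tx <- toy_transcriptome(list(c("ATG", "GCT", "GAA", "TAA"),
                               c("ATG", "GCT", "GAA", "TAA")))
  asn <- fake_assignments(
    rep(c("t01", "t02"), each = 8),
    c(rep(0, 2), rep(2, 4), rep(3, 2),     # D = [1,0,2,1]
      rep(0, 2), rep(1, 4), rep(3, 2)))    # D = [1,2,0,1]
  mp <- metagene_profile(asn, tx, "start", window = 4,
                         min_reads = 1, min_len = 4)
  expect_equal(mp$A, c(1, 1, 1, 1))
  expect_equal(mp$N, rep(2L, 4))
  ms <- metagene_profile(asn, tx, "stop", window = 4,
                         min_reads = 1, min_len = 4)
  expect_equal(ms$A, c(1, 1, 1, 1))
  expect_error(metagene_profile(asn, tx, "start", window = 4,
                                min_reads = 1000, min_len = 4),
               "no genes pass")
})

test_that("metagene_profile is invariant to scaling any gene's reads", {
  cfg <- sim_config(seed = 13, n_genes = 40, orf_length = c(200, 300),
                    total_footprints = 2e5)
  tx <- simulate_transcriptome(cfg)
  sim <- simulate_footprints(tx, cfg)
  asn <- assign_sites(sim$alignments, tx)
  mp1 <- metagene_profile(asn, tx, "start", window = 50, min_len = 50)
  # triplicate every read of one gene: its density rows are unchanged
  dup <- asn[asn$transcript_id == "g0001", ]
  asn2 <- rbind(asn, dup, dup)
  mp2 <- metagene_profile(asn2, tx, "start", window = 50, min_len = 50)
  expect_equal(mp2$A, mp1$A, tolerance = 1e-12)
})

test_that("start accumulation elevates only the first metagene offsets", {
  cfg <- sim_config(seed = 14, n_genes = 150, orf_length = c(200, 300),
                    total_footprints = 8e5, expression_sdlog = 0,
                    start_boost = 3)
  tx <- simulate_transcriptome(cfg)
  sim <- simulate_footprints(tx, cfg)
  asn <- assign_sites(sim$alignments, tx)
  mp <- metagene_profile(asn, tx, "start", window = 100, min_len = 100)
  expect_true(all(mp$A[1:3] > 2))
  expect_lt(max(mp$A[10:100]), 1.05)
})

test_that("wave_profile is exactly 1 for a uniform single-gene density", {
  codons <- c("ATG", rep("GCT", 198), "TAA")
  codons[51] <- "CGA"
  tx <- toy_transcriptome(list(codons))
  asn <- fake_assignments("t01", 0:199)    # one read per codon
  wp <- wave_profile(asn, tx, "CGA", min_reads = 64)
  expect_equal(attr(wp, "n_occurrences"), 1L)
  expect_equal(wp$enrichment, rep(1, nrow(wp)))
  expect_error(wave_profile(asn, tx, "CGT", min_reads = 64),
               "no usable occurrences")
  expect_error(wave_profile(asn, tx, "TAA"), "sense codon")
})

test_that("occurrences near the ORF edges are skipped", {
  codons <- c("ATG", rep("GCT", 198), "TAA")
  codons[c(6, 51, 198)] <- "CGA"           # codons 5, 50, 197
  tx <- toy_transcriptome(list(codons))
  asn <- fake_assignments("t01", 0:199)
  wp <- wave_profile(asn, tx, "CGA", min_reads = 64, exclude_edges = 20)
  expect_equal(attr(wp, "n_occurrences"), 1L)  # only codon 50 is interior
})

test_that("a no-wave dwell model yields flat profiles for every codon", {
  cfg <- sim_config(seed = 15, n_genes = 120, orf_length = c(200, 300),
                    total_footprints = 1e6, expression_sdlog = 0)
  tx <- simulate_transcriptome(cfg)
  sim <- simulate_footprints(tx, cfg)
  asn <- assign_sites(sim$alignments, tx)
  wp <- wave_profiles(asn, tx, d_min = -10, d_max = 30)
  expect_equal(sort(unique(wp$codon)), sense_codons)
  dev <- abs(wp$enrichment - 1)
  expect_lt(max(dev, na.rm = TRUE), 0.15)
  expect_lt(mean(dev, na.rm = TRUE), 0.03)
})
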