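test_that("codon occupancy matches the hand-computed single-gene case", {
  # 10 retained codons, all distinct; 2 reads at the single GAA, 1 at
  # each of the other 9 -> occupancy(GAA) = 2 * 10/11, others 10/11
  cods <- c("ATG", "GAA", "GCT", "TGT", "CAT", "AAA", "CCC", "GGG",
            "TTT", "CGA")
  tx <- toy_transcriptome(list(cods))
  asn <- fake_assignments("t01", c(0:9, 1))    # extra read at GAA (codon 1)
  occ <- codon_occupancy(asn, tx, "A", min_reads = 0,
                         exclude_first = 0, exclude_last = 0)
  get <- function(c) occ$occupancy[occ$codon == c]
  expect_equal(get("GAA"), 20 / 11)
  expect_equal(get("GCT"), 10 / 11)
  expect_equal(get("ATG"), 10 / 11)
  expect_true(is.na(get("AGG")))               # absent codon: missing, not 0
  expect_equal(occ$n_reads[occ$codon == "GAA"], 2L)
  # position-weighted mean occupancy is 1 by construction
  wm <- sum(occ$occupancy * occ$n_positions, na.rm = TRUE) /
    sum(occ$n_positions)
  expect_equal(wm, 1, tolerance = 1e-9)
})

test_that("P- and E-site occupancy look up the codon upstream of the A site", {
  cods <- c("ATG", "GAA", "GCT", "TGT", "CAT", "AAA", "CCC", "GGG",
            "TTT", "CGA")
  tx <- toy_transcriptome(list(cods))
  asn <- fake_assignments("t01", c(2, 2, 3))   # density at codons 2 and 3
  occ_p <- codon_occupancy(asn, tx, "P", min_reads = 0,
                           exclude_first = 2, exclude_last = 0)
  # retained positions 2..9 renormalize to n=8 over 3 reads;
  # position 2 (P codon GAA) has D = 2*8/3
  expect_equal(occ_p$occupancy[occ_p$codon == "GAA"], 16 / 3)
  expect_equal(occ_p$occupancy[occ_p$codon == "GCT"], 8 / 3)
  expect_error(codon_occupancy(asn, tx, "B"), "arg")
})

test_that("occupancy is invariant to scaling a gene's read counts", {
  cfg <- sim_config(seed = 31, n_genes = 30, orf_length = c(150, 250),
                    total_footprints = 2e5)
  tx <- simulate_transcriptome(cfg)
  sim <- simulate_footprints(tx, cfg)
  asn <- assign_sites(sim$alignments, tx)
  o1 <- codon_occupancy(asn, tx, "A")
  dup <- asn[asn$transcript_id == "g0002", ]
  o2 <- codon_occupancy(rbind(asn, dup, dup), tx, "A")
  expect_equal(o2$occupancy, o1$occupancy, tolerance = 1e-12)
})

test_that("flat-dwell occupancy is near 1 and stop rows are excluded from comparisons", {
  cfg <- sim_config(seed = 32, n_genes = 100, orf_length = c(200, 300),
                    total_footprints = 1e6, expression_sdlog = 0)
  tx <- simulate_transcriptome(cfg)
  sim <- simulate_footprints(tx, cfg)
  asn <- assign_sites(sim$alignments, tx)
  occ <- codon_occupancy(asn, tx, "A")
  sense <- occ[!occ$codon %in% c("TAA", "TAG", "TGA"), ]
  expect_true(all(abs(sense$occupancy - 1) < 0.05))
  # stop codons never sit in the A site inside the trimmed ORF body
  stops <- occ[occ$codon %in% c("TAA", "TAG", "TGA"), ]
  expect_true(all(is.na(stops$occupancy)))
  cmp <- compare_occupancy(occ, occ)
  expect_equal(cmp$n, 61L)
})

test_that("compare_occupancy yields signed R2 of 1 for self and -1 for mirrored tables", {
  cfg <- sim_config(seed = 33, n_genes = 40, orf_length = c(150, 250),
                    total_footprints = 3e5, dwell_sdlog = 0.3)
  tx <- simulate_transcriptome(cfg)
  sim <- simulate_footprints(tx, cfg)
  asn <- assign_sites(sim$alignments, tx)
  occ <- codon_occupancy(asn, tx, "A")
  self <- compare_occupancy(occ, occ)
  expect_equal(self$signed_R2, 1, tolerance = 1e-12)
  expect_lt(self$p_value, 1e-10)
  expect_false(self$crossed_out)

  mirrored <- occ
  mirrored$occupancy <- 2 - occ$occupancy
  anti <- compare_occupancy(occ, mirrored)
  expect_equal(anti$signed_R2, -1, tolerance = 1e-12)

  occ_p <- codon_occupancy(asn, tx, "P")
  expect_error(compare_occupancy(occ, occ_p), "different ribosomal sites")

  few <- occ
  few$occupancy[!few$codon %in% c("GCT", "GAA", "TGT")] <- NA
  expect_error(compare_occupancy(occ, few), "fewer than 4")
})
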