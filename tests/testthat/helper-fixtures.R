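# Shared fixtures and independent oracles for the test suite.

sense_codons <- setdiff(
  sort(as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"), paste0),
                       c("A","C","G","T"), paste0))),
  c("TAA", "TAG", "TGA"))

# A transcriptome built from an explicit codon list (plus UTRs), so tests
# know exactly which codon sits at every position.
toy_transcriptome <- function(codons_list, utr5 = 30L, utr3 = 30L) {
  ids <- sprintf("t%02d", seq_along(codons_list))
  seqs <- vapply(codons_list, function(cod) {
    paste0(strrep("C", utr5), paste(cod, collapse = ""), strrep("A", utr3))
  }, character(1))
  anno <- data.frame(
    transcript_id = ids,
    cds_start = utr5,
    cds_end = utr5 + 3L * lengths(codons_list))
  transcriptome(setNames(seqs, ids), anno)
}

# Fake site assignments with the columns the analysis functions contract
# on; one row per read.
fake_assignments <- function(transcript_id, a_site_codon,
                             footprint_class = "long") {
  data.frame(transcript_id = transcript_id,
             five_prime = 0L, length = 30L,
             footprint_class = footprint_class,
             frame_class = "frame0",
             a_site_codon = as.integer(a_site_codon),
             stringsAsFactors = FALSE)
}

# Independent per-read site-assignment oracle: locate the A-site
# nucleotides inside the footprint (positions 16-18 for frame-0 5' ends,
# 17-19 for frame -1, 1-based), then translate each nucleotide to a codon
# index via the transcript's codon grid and check all three agree.
oracle_assign <- function(alignments, tx,
                          long = c(29L, 31L), short = c(21L, 22L)) {
  n <- nrow(alignments)
  keep <- logical(n)
  cls <- chr <- frc <- character(n)
  asite <- integer(n)
  for (r in seq_len(n)) {
    id <- alignments$transcript_id[r]
    an <- tx$anno[tx$anno$transcript_id == id, ]
    p <- alignments$five_prime[r]
    len <- alignments$length[r]
    if (len >= long[1] && len <= long[2]) cls[r] <- "long"
    else if (len >= short[1] && len <= short[2]) cls[r] <- "short"
    else next
    fr <- (p - an$cds_start) %% 3
    if (fr == 1) next
    nt0 <- if (fr == 0) p + 15 else p + 16   # first A-site nt, 0-based
    cods <- floor(((nt0 + 0:2) - an$cds_start) / 3)
    stopifnot(cods[1] == cods[2], cods[2] == cods[3])
    a <- cods[1]
    if (a < -6 || a > an$cds_codons + 6) next
    keep[r] <- TRUE
    frc[r] <- if (fr == 0) "frame0" else "frameMinus1"
    asite[r] <- as.integer(a)
  }
  data.frame(
    transcript_id = alignments$transcript_id[keep],
    five_prime = alignments$five_prime[keep],
    length = alignments$length[keep],
    footprint_class = cls[keep],
    frame_class = frc[keep],
    a_site_codon = asite[keep],
    stringsAsFactors = FALSE)
}

# Brute-force substring scan used as the mapping oracle.
oracle_map <- function(read, tx) {
  hits <- NULL
  for (id in names(tx$sequences)) {
    p <- gregexpr(read, tx$sequences[[id]], fixed = TRUE)[[1]]
    if (p[1] != -1)
      hits <- rbind(hits, data.frame(transcript_id = id, five_prime = p - 1L))
  }
  hits
}
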