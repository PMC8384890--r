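Package: riboscope
Title: Codon-Level Analysis of Ribosome Profiling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for codon-resolution analysis of ribosome profiling
    (Ribo-seq) libraries in transcript coordinates: adapter clipping and
    randomized-linker trimming, exact-match mapping of footprints to a
    reference transcriptome, footprint length and reading-frame quality
    control, frame-dependent assignment of footprints to ribosomal A-, P-
    and E-site codons, per-gene ribosome density normalization, metagene
    profiles of the 5' translation ramp, transcriptome-wide codon dwell-time
    occupancy with cross-condition comparison by signed R-squared,
    codon-anchored downstream enrichment ("wave") profiles, and gene-level
    and 5'-UTR count matrices ready for differential analysis. Includes a
    fully parameterized generator of synthetic transcriptomes and footprint
    libraries (bimodal footprint lengths, frame periodicity, codon-specific
    dwell weights, translation ramp, start/stop accumulation, injectable
    downstream waves) so that every analysis stage can be validated against
    a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
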