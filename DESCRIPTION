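Package: nucphase
Title: Nucleosome Phasing Analysis from Paired-End MNase-Seq Fragments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of nucleosome positioning from paired-end MNase-seq
    fragment data. Implements the inter-nucleosome distance auto-correlation
    (DAC) and cross-correlation (DCC) functions with multiplicity or
    coincidence weighting, peak detection and linear-regression estimation of
    the nucleosome repeat length and the DNA helical period, normalized
    occupancy tracks and TSS-aligned composite profiles, dyad-position
    histograms, WW/SS dinucleotide periodicity profiles with linker extension
    and dyad symmetrization, micrococcal-nuclease end-cleavage consensus and
    end-bias robustness filtering, and a cell-ensemble nucleosome array
    simulator with configurable spacing mixtures, rotational position
    clusters, planted sequence periodicity and biased cut sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    jsonlite,
    optparse,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
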