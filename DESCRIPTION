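Package: dgrscope
Title: Discovery and Characterization of Diversity-Generating Retroelements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects diversity-generating retroelements (DGRs) in genome and
    contig sequences by scanning for reverse-transcriptase-like open reading
    frames, discovering proximal repeat pairs, and classifying template/variable
    repeats (TR/VR) by adenine-specific mismatch criteria. Characterizes
    cis-acting elements (IMH/IMH* terminal motifs, stem-loop hairpins with
    constrained loops, Avd-like accessory ORFs selected by isoelectric point and
    molecular weight), quantifies the theoretical diversification potential of a
    target protein under adenine mutagenesis with exact integer arithmetic, and
    performs sliding-window tetranucleotide composition analysis with non-metric
    multidimensional scaling and confidence-ellipse outlier reporting. Includes
    a synthetic-genome generator that plants complete DGR cassettes with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vegan,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
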