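Package: lethalscan
Title: Mapping Recessive Embryonic-Lethal Deletions and Quantifying Their
    Fertility Impact
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the inference chain used to characterise recessive
    embryonic-lethal deletions in livestock: autozygosity mapping of a
    shared homozygous haplotype in affected individuals with a Monte-Carlo
    genome-wide significance test, structural-variant deletion calling from
    discordant mate-pair clusters and coverage dropout with exact breakpoint
    refinement from junction-bridging reads, prediction of transcript and
    protein consequences (frameshift, premature termination,
    nonsense-mediated decay, validation amplicons), Hardy-Weinberg
    carrier-frequency arithmetic, and estimation of in-utero mortality of
    homozygous conceptuses from mating-class return-to-oestrus contrasts.
    Includes seeded simulators for every input so the whole pipeline can be
    exercised end to end on synthetic data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
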