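Package: consortia
Title: Full Factorial Assembly and Community-Function Landscapes of
    Synthetic Microbial Consortia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the full factorial construction of synthetic microbial
    consortia with multichannel pipettes and standard microtiter plates, and
    for the analysis of the resulting community-function landscapes. Each
    consortium from an m-species library is identified by a binary code that
    maps bijectively onto plate wells, so that all 2^m combinations can be
    assembled with far fewer liquid-handling events than the naive m*2^(m-1).
    The package generates plate layouts, volume-accounted pipetting plans with
    density homogenization, and machine-readable worklists, and verifies them
    with a deterministic liquid-transfer simulator. Downstream analytics cover
    additive spectral expectations and deviation statistics, functional effects
    and pairwise and third-order interactions on the composition hypercube,
    variance decomposition by interaction order (Walsh-Hadamard basis), global
    epistasis regressions with a permutation null, and synthetic-data
    generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
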