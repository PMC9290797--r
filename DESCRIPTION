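Package: zapscan
Title: Admixture and Selection Scans for Invasion Genomics
Version: 0.1.0
Authors@R: person("Avery", "Comstock", email = "avery.comstock@example.org",
    role = c("aut", "cre"))
Description: Window-based population-genomic toolkit for studying recently
    introduced populations descended from an admixed source. Provides
    coverage-based sex-chromosome scaffold assignment, windowed nucleotide
    diversity and Hudson F_ST, the population branch statistic (PBS),
    topology weighting over per-window neighbour-joining trees with a
    west-minus-east ancestry score, four-population f4 tests with block
    jackknife standard errors, percentile outlier scans with an
    overlap-randomization null, and a Balding-Nichols synthetic-data
    generator emulating a shared admixture-then-colonization history, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    data.table,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
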