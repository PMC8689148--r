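Package: popld
Title: Linkage Disequilibrium, LD-Phase Persistence, and LD-Based
    Effective Population Size from SNP-Array Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the classic SNP-array population-genetics workflow on
    small livestock samples: per-population genotype quality control
    (call-rate, minor allele frequency, Hardy-Weinberg exact test) followed by
    a common-marker merge; pairwise linkage disequilibrium statistics (D, D',
    r, r squared) with the finite-sample correction r2 - 1/(beta*n);
    adjacent-marker LD summaries and distance-binned LD decay curves;
    persistence of LD phase between populations as the per-distance-bin
    correlation of signed r; and effective population size trajectories via
    Sved's relation with the T = 1/(2c) generation mapping.  Includes a
    seedable Wright-Fisher forward simulator with recombination and population
    splits so every stage can be exercised and calibrated on data with known
    truth, plus readers and writers for binary and text PLINK filesets and
    VCF.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
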