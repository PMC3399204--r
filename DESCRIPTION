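Package: islandpop
Title: Genetic Diversity and Abundance Assessment for Small Island Populations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the conservation status of small, isolated
    vertebrate populations from codominant microsatellite genotypes and
    live-capture records.  Implements GenePop-dialect genotype input and
    output, per-population diversity statistics (observed and unbiased
    expected heterozygosity, rarefied allelic richness, rare and private
    alleles, Weir-Cockerham F-statistics, exact Hardy-Weinberg tests,
    pairwise F_ST with bootstrap intervals and permutation tests),
    closed-population mark-recapture abundance estimation by Huggins
    conditional likelihood with AIC model selection and population-closure
    tests, Wright-Fisher Monte-Carlo forecasting of heterozygosity and
    allelic loss under drift, and closed-form effective-population-size and
    effective-inbreeding estimators.  Seed-deterministic generators for
    genotype sets and capture histories with known truth support validation
    of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown, withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
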