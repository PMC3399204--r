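test_that("observed heterozygosity is the heterozygote fraction", {
  gm <- handGenotypes(list(p = list(c(1L, 2L), c(1L, 2L))), "L1")
  expect_equal(observedHeterozygosity(gm, "p")$mean, 1)
  gmHom <- handGenotypes(list(p = list(c(1L, 1L), c(2L, 2L))), "L1")
  expect_equal(observedHeterozygosity(gmHom, "p")$mean, 0)
  # direct count on a random fixture
  gmR <- generateGenotypes("r", 50, toyFreqs(), seed = 31,
                           missingRate = 0.08)
  calls <- genotypeCalls(gmR)
  direct <- vapply(seq_along(loci(gmR)), function(l) {
    ok <- !is.na(calls$a[, l])
    mean(calls$a[ok, l] != calls$b[ok, l])
  }, numeric(1))
  expect_equal(unname(observedHeterozygosity(gmR, "r")$perLocus), direct)
})

test_that("expected heterozygosity uses the unbiased small-sample factor", {
  gmMono <- handGenotypes(list(p = list(c(1L, 1L), c(1L, 1L))), "L1")
  expect_equal(expectedHeterozygosity(gmMono, "p")$mean, 0)
  # n = 2 genotypes, both (1,2): p = (0.5, 0.5), HE = (4/3) * 0.5
  gm <- handGenotypes(list(p = list(c(1L, 2L), c(1L, 2L))), "L1")
  expect_equal(expectedHeterozygosity(gm, "p")$mean, 2 / 3,
               tolerance = 1e-12)
  # asymptotics: large simulated n at p = (0.5, 0.5)
  gmBig <- generateGenotypes("b", 5000, list(L1 = c(`1` = .5, `2` = .5)),
                             seed = 17)
  expect_equal(expectedHeterozygosity(gmBig, "b")$mean, 0.5,
               tolerance = 0.02)
  # a single-genotype locus is excluded with a warning
  gmOne <- handGenotypes(list(p = list(c(1L, 2L, 1L, 2L),
                                       c(1L, 1L, NA, NA))),
                         c("L1", "L2"))
  expect_warning(he <- expectedHeterozygosity(gmOne, "p"), "excluded")
  expect_true(is.na(he$perLocus["L2"]))
})

test_that("rarefied richness matches exhaustive subsampling on a toy locus", {
  # 6 genes: alleles 1,1,1,2,2,3 (three individuals)
  gm <- handGenotypes(list(p = list(c(1L, 1L), c(1L, 2L), c(2L, 3L))), "L1")
  genes <- c(1, 1, 1, 2, 2, 3)
  for (g in 2:6) {
    combos <- combn(6, g)
    exhaustive <- mean(apply(combos, 2,
                             function(ix) length(unique(genes[ix]))))
    expect_equal(allelicRichness(gm, "p", g = g)$mean, exhaustive,
                 tolerance = 1e-12)
  }
  # full-sample rarefaction returns the observed allele count
  expect_equal(allelicRichness(gm, "p", g = 6)$mean, 3)
  # monomorphic locus has richness 1 at any g
  gmMono <- handGenotypes(list(p = list(c(1L, 1L), c(1L, 1L))), "L1")
  expect_equal(allelicRichness(gmMono, "p", g = 2)$mean, 1)
  expect_equal(allelicRichness(gmMono, "p", g = 4)$mean, 1)
})

test_that("richness is non-decreasing in the subsample size", {
  gm <- generateGenotypes("r", 20, calibratedFrequencies(), seed = 44)
  rs <- vapply(seq(2, 40, by = 2), function(g)
    allelicRichness(gm, "r", g = g)$mean, numeric(1))
  expect_true(all(diff(rs) >= -1e-12))
  expect_error(allelicRichness(gm, "r", g = 42), "exceeds the gene count")
})

test_that("F-statistics match an independent ANOVA-mean-squares oracle", {
  set.seed(202)
  gm <- bindPopulations(
    generateGenotypes("p1", 10, toyFreqs(), fis = 0.15, seed = 51),
    generateGenotypes("p2", 10, list(L1 = c(`1` = 0.2, `2` = 0.5, `3` = 0.3),
                                     L2 = c(`1` = 0.9, `2` = 0.1),
                                     L3 = c(`1` = 1.0),
                                     L4 = c(`1` = 0.7, `4` = 0.3)),
                      seed = 52))
  got <- wcFstats(gm)
  oracle <- msFstOracle(gm, c("p1", "p2"))
  expect_equal(got$FST, oracle$FST, tolerance = 1e-10)
  expect_equal(got$FIS, oracle$FIS, tolerance = 1e-10)
})

test_that("complete fixation gives a per-locus F_ST of one", {
  gm <- handGenotypes(list(
    a = list(c(1L, 1L), c(1L, 1L), c(1L, 1L)),
    b = list(c(2L, 2L), c(2L, 2L), c(2L, 2L))), "L1")
  res <- wcFstats(gm)
  expect_equal(res$perLocus$FST, 1)
  expect_equal(res$FST, 1)
})

test_that("a random-mating population has near-zero multilocus F_IS", {
  gm <- generateGenotypes("hwe", 5000, calibratedFrequencies(), seed = 77)
  expect_lt(abs(wcFstats(gm, "hwe")$FIS), 0.02)
})

test_that("F-statistics error cleanly when all loci are monomorphic", {
  gm <- handGenotypes(list(a = list(c(1L, 1L)), b = list(c(1L, 1L))), "L1")
  expect_error(wcFstats(gm), "monomorphic")
})

test_that("statistics are invariant to individual order and relabeling", {
  gm <- bindPopulations(
    generateGenotypes("a", 15, toyFreqs(), seed = 61),
    generateGenotypes("b", 12, toyFreqs(), fis = 0.3, seed = 62))
  perm <- c(16:27, 1:15)  # population b first
  gmP <- islandpop:::newGenotypeMatrix(
    individuals(gm)[perm], loci(gm), populations(gm)[perm],
    genotypeCalls(gm)$a[perm, , drop = FALSE],
    genotypeCalls(gm)$b[perm, , drop = FALSE])
  expect_equal(wcFstats(gm)$FST, wcFstats(gmP)$FST, tolerance = 1e-12)
  expect_equal(expectedHeterozygosity(gm, "a")$mean,
               expectedHeterozygosity(gmP, "a")$mean, tolerance = 1e-12)
  # allele relabeling (1,2,3,4) -> (40,10,30,20)
  relab <- c(40L, 10L, 30L, 20L)
  a2 <- matrix(relab[genotypeCalls(gm)$a], nrow = nInd(gm))
  b2 <- matrix(relab[genotypeCalls(gm)$b], nrow = nInd(gm))
  gmL <- islandpop:::newGenotypeMatrix(individuals(gm), loci(gm),
                                       populations(gm), a2, b2)
  expect_equal(wcFstats(gm)$FST, wcFstats(gmL)$FST, tolerance = 1e-12)
  expect_equal(allelicRichness(gm, "b", g = 10)$mean,
               allelicRichness(gmL, "b", g = 10)$mean, tolerance = 1e-12)
})

test_that("signed-rank comparison matches the exact reference distribution", {
  expect_true(is.na(wilcoxonRichness(1:13, 1:13)))
  # a uniform +1 shift across 13 loci attains the extreme two-sided p
  expect_equal(wilcoxonRichness(1:13 + 1, 1:13), 2 / 2^13,
               tolerance = 1e-12)
  # tie-free paired vectors agree with the exact signed-rank reference
  set.seed(5)
  for (k in 1:8) {
    n <- sample(4:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
    expect_equal(wilcoxonRichness(x, y), ref, tolerance = 1e-10)
  }
})

test_that("population summaries assemble coherently", {
  # population of identical homozygous clones
  gmClones <- handGenotypes(list(c1 = lapply(1:5, function(i)
    c(3L, 3L, 2L, 2L))), c("L1", "L2"))
  s <- populationSummary(gmClones, "c1")
  expect_equal(s@a, 1); expect_equal(s@r, 1)
  expect_equal(s@HO, 0); expect_equal(s@HE, 0)
  expect_true(is.na(s@FIS))
  expect_equal(s@monomorphicLoci, 2L)
  # a synthetic random-mating population has HO close to HE
  gm <- generateGenotypes("hw", 400, calibratedFrequencies(), seed = 91)
  s2 <- populationSummary(gm, "hw", hweSteps = 500)
  expect_lt(abs(s2@HO - s2@HE), 0.03)
  expect_lt(abs(s2@FIS), 0.05)
  # severely bottlenecked island fixture: exactly 8 monomorphic loci
  relict <- depauperateIslandFixture()
  sR <- populationSummary(relict, "relict", hweSteps = 500)
  expect_equal(sR@monomorphicLoci, 8L)
  expect_lt(sR@HE, 0.15)
})

test_that("Fisher-combined uniform p-values stay uniform", {
  set.seed(12)
  combined <- replicate(400, {
    ps <- runif(13)
    pchisq(-2 * sum(log(ps)), df = 26, lower.tail = FALSE)
  })
  expect_gt(suppressWarnings(stats::ks.test(combined, "punif"))$p.value,
            0.01)
})
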