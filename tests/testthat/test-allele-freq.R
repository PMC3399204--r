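test_that("allele counting follows the two-genes-per-genotype rule", {
  gm <- handGenotypes(list(p = list(c(1L, 1L), c(1L, 2L))), "L1")
  aft <- alleleFrequencies(gm)
  t <- freqTable(aft)
  expect_equal(t$freq[t$allele == 1], 0.75)
  expect_equal(t$freq[t$allele == 2], 0.25)
  expect_equal(geneCounts(aft)["p", "L1"], 4L)

  gmMiss <- handGenotypes(list(p = list(c(1L, 1L), c(NA, NA))), "L1")
  aftM <- alleleFrequencies(gmMiss)
  expect_equal(freqTable(aftM)$freq, 1)
  expect_equal(geneCounts(aftM)["p", "L1"], 2L)
})

test_that("sampled frequencies recover the generator truth at large n", {
  p <- c(`1` = 0.6, `2` = 0.3, `3` = 0.1)
  gm <- generateGenotypes("big", 10000, list(L1 = p), seed = 99)
  aft <- alleleFrequencies(gm)
  t <- freqTable(aft)
  nGenes <- 20000
  for (al in names(p)) {
    se <- sqrt(p[[al]] * (1 - p[[al]]) / nGenes)
    expect_lt(abs(t$freq[t$allele == as.integer(al)] - p[[al]]),
              qnorm(0.995) * se * 1.5 + 1e-9)
  }
})

test_that("frequencies sum to one and respect monotone gene counts", {
  freqs <- toyFreqs()
  gm <- bindPopulations(
    generateGenotypes("a", 30, freqs, missingRate = 0.1, seed = 5),
    generateGenotypes("b", 20, freqs, seed = 6))
  aft <- alleleFrequencies(gm)
  t <- freqTable(aft)
  sums <- tapply(t$freq, paste(t$population, t$locus), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(geneCounts(aft) %% 2 == 0))
  # dropping an individual never increases any gene count
  gm2 <- islandpop:::newGenotypeMatrix(
    individuals(gm)[-1], loci(gm), populations(gm)[-1],
    genotypeCalls(gm)$a[-1, , drop = FALSE],
    genotypeCalls(gm)$b[-1, , drop = FALSE])
  expect_true(all(geneCounts(alleleFrequencies(gm2))["a", ] <=
                    geneCounts(aft)["a", ]))
})

test_that("private alleles are exactly the planted ones", {
  # plant allele 9 at L1 and allele 7 at L2 only in the focal population
  gm <- handGenotypes(list(
    focal = list(c(1L, 9L, 7L, 7L), c(1L, 1L, 1L, 2L)),
    ref1  = list(c(1L, 2L, 1L, 2L), c(1L, 1L, 2L, 2L)),
    ref2  = list(c(2L, 2L, 1L, 1L), c(1L, 2L, 1L, 2L))),
    c("L1", "L2"))
  aft <- alleleFrequencies(gm)
  pa <- privateAlleles(aft, "focal", c("ref1", "ref2"))
  expect_equal(pa$L1, 9L)
  expect_equal(pa$L2, 7L)
  # a population compared with an identical copy has no private alleles
  gmDup <- handGenotypes(list(
    x = list(c(1L, 2L, 3L, 3L)), y = list(c(1L, 2L, 3L, 3L))),
    c("L1", "L2"))
  paDup <- privateAlleles(alleleFrequencies(gmDup), "x", "y")
  expect_true(all(lengths(paDup) == 0))
  expect_error(privateAlleles(aft, "nope", "ref1"), "unknown population")
})

test_that("rare-allele counting is boundary-inclusive and matches brute force", {
  # locus with freqs 0.95/0.05: the 0.05 allele counts as rare
  gm <- handGenotypes(list(p = lapply(1:10, function(i)
    if (i == 1) c(1L, 2L) else c(1L, 1L))), "L1")
  aft <- alleleFrequencies(gm)
  ra <- rareAlleles(aft, "p", threshold = 0.05)
  expect_equal(unname(ra$perLocus["L1"]), 1L)
  # monomorphic locus contributes zero
  gmMono <- handGenotypes(list(p = list(c(1L, 1L), c(1L, 1L))), "L1")
  expect_equal(unname(rareAlleles(alleleFrequencies(gmMono), "p")$perLocus),
               0L)
  # brute force over a random table
  gmR <- generateGenotypes("r", 40, calibratedFrequencies(), seed = 21)
  aftR <- alleleFrequencies(gmR)
  tt <- freqTable(aftR)
  brute <- vapply(loci(aftR), function(l) {
    f <- tt$freq[tt$locus == l]
    sum(f > 0 & f <= 0.05)
  }, integer(1))
  raR <- rareAlleles(aftR, "r")
  expect_equal(raR$perLocus, brute)
  expect_equal(raR$mean, mean(brute))
  expect_equal(raR$sd, sd(brute))
})

test_that("mean alleles per locus equals independently counted set sizes", {
  gm <- handGenotypes(list(p = list(c(1L, 1L, 1L, 2L), c(1L, 2L, 3L, 4L))),
                      c("L1", "L2"))
  ma <- meanAllelesPerLocus(alleleFrequencies(gm), "p")
  expect_equal(unname(ma$perLocus), c(2L, 4L))
  expect_equal(ma$mean, 3)
  gmMono <- generateGenotypes("m", 10,
                              setNames(rep(list(c(`1` = 1)), 13),
                                       sprintf("L%02d", 1:13)), seed = 1)
  expect_equal(meanAllelesPerLocus(alleleFrequencies(gmMono), "m")$mean, 1)
  # independently: distinct calls per locus on a random fixture
  gmR <- generateGenotypes("r", 25, calibratedFrequencies(), seed = 8)
  calls <- genotypeCalls(gmR)
  sizes <- vapply(seq_along(loci(gmR)), function(l)
    length(unique(c(calls$a[, l], calls$b[, l]))), integer(1))
  expect_equal(meanAllelesPerLocus(alleleFrequencies(gmR), "r")$mean,
               mean(sizes))
})
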