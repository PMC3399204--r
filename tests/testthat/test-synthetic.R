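test_that("generators are exactly seed-deterministic", {
  a <- generateGenotypes("p", 30, toyFreqs(), fis = 0.1, missingRate = 0.05,
                         seed = 4)
  b <- generateGenotypes("p", 30, toyFreqs(), fis = 0.1, missingRate = 0.05,
                         seed = 4)
  expect_identical(genotypeCalls(a), genotypeCalls(b))
  c <- generateGenotypes("p", 30, toyFreqs(), fis = 0.1, missingRate = 0.05,
                         seed = 5)
  expect_false(identical(genotypeCalls(a), genotypeCalls(c)))
  s1 <- generateCaptureHistories(50, 6, cmrModelSpec(), 0, seed = 8)
  s2 <- generateCaptureHistories(50, 6, cmrModelSpec(), 0, seed = 8)
  expect_identical(detections(s1$history), detections(s2$history))
  f1 <- founderBottleneck(toyFreqs(), seed = 12)
  f2 <- founderBottleneck(toyFreqs(), seed = 12)
  expect_identical(genotypeCalls(f1), genotypeCalls(f2))
})

test_that("random mating yields Hardy-Weinberg heterozygosity", {
  freqs <- calibratedFrequencies()
  gm <- generateGenotypes("p", 4000, freqs, seed = 6)
  hexp <- vapply(freqs, function(p) 1 - sum(p^2), numeric(1))
  ho <- observedHeterozygosity(gm, "p")
  expect_equal(ho$mean, mean(hexp), tolerance = 0.01)
  # full inbreeding collapses heterozygosity to ~0
  gmF <- generateGenotypes("f", 500, freqs, fis = 0.999, seed = 6)
  expect_lt(observedHeterozygosity(gmF, "f")$mean, 0.01)
  # intermediate fis reduces HO to about (1 - fis) * HE
  gmH <- generateGenotypes("h", 4000, freqs, fis = 0.4, seed = 16)
  expect_equal(observedHeterozygosity(gmH, "h")$mean, 0.6 * mean(hexp),
               tolerance = 0.015)
})

test_that("missingness hits the requested rate and stays genotype-wise", {
  gm <- generateGenotypes("p", 2000, toyFreqs(), missingRate = 0.2, seed = 9)
  calls <- genotypeCalls(gm)
  expect_equal(mean(is.na(calls$a)), 0.2, tolerance = 0.02)
  # a and b are missing together, never singly
  expect_identical(is.na(calls$a), is.na(calls$b))
})

test_that("the founder bottleneck loses diversity on the expected scale", {
  freqs <- calibratedFrequencies()
  H0 <- mean(vapply(freqs, function(p) 1 - sum(p^2), numeric(1)))
  # defaults: 16 founders, Ne = 11, 7 generations.  The founder event is
  # roughly one extra drift generation at Ne = 16, so
  # E[H] ~ H0 (1 - 1/32) (1 - 1/22)^7
  target <- H0 * (1 - 1 / 32) * (1 - 1 / 22)^7
  he <- vapply(1:30, function(s) {
    gm <- founderBottleneck(freqs, seed = s, sampleSize = 40)
    suppressWarnings(expectedHeterozygosity(gm, "island")$mean)
  }, numeric(1))
  expect_lt(abs(mean(he) - target), 0.05)
  # diversity was actually lost, and alleles only ever disappear
  expect_lt(mean(he), H0)
  gm <- founderBottleneck(freqs, seed = 2)
  src <- generateGenotypes("src", 200, freqs, seed = 3)
  aftI <- alleleFrequencies(gm)
  expect_true(all(alleleCounts(aftI)["island", ] <=
                    vapply(freqs, length, integer(1))))
})

test_that("structured generation creates measurable differentiation", {
  gm <- generateStructuredPops(toyFreqs(), fst = 0.3,
                               popSizes = c(i1 = 60, i2 = 60, i3 = 60),
                               seed = 20)
  expect_equal(sort(unique(populations(gm))), c("i1", "i2", "i3"))
  theta <- wcFstats(gm)$FST
  expect_gt(theta, 0.08)
  expect_error(generateStructuredPops(toyFreqs(), fst = 0,
                                      popSizes = c(a = 10, b = 10)),
               "fst must lie")
})

test_that("capture simulation truth matches its observable consequences", {
  # certain detection: every animal is caught on every occasion
  sim <- generateCaptureHistories(25, 4, cmrModelSpec(), qlogis(1 - 1e-12),
                                  seed = 5)
  expect_equal(nInd(sim$history), 25L)
  expect_true(all(detections(sim$history) == 1L))
  expect_true(all(sim$truth$detected))
  # detection count concentrates near N * (1 - (1-p)^T)
  p <- 0.3; T <- 10
  nDet <- vapply(1:40, function(s)
    nInd(generateCaptureHistories(100, T, cmrModelSpec(), qlogis(p),
                                  seed = 300 + s)$history), numeric(1))
  expected <- 100 * (1 - (1 - p)^T)
  expect_lt(abs(mean(nDet) - expected), 1.5)
  # trap-happy behavior raises recapture rates above first-capture rates
  simB <- generateCaptureHistories(400, 8,
                                   cmrModelSpec(behavior = TRUE),
                                   c(qlogis(0.2), 1.5), seed = 6)
  y <- detections(simB$history)
  first <- apply(y, 1, function(r) which(r == 1)[1])
  afterRate <- mean(unlist(lapply(seq_len(nrow(y)), function(i)
    if (first[i] < ncol(y)) y[i, (first[i] + 1):ncol(y)] else NULL)))
  expect_gt(afterRate, 0.35)  # plogis(qlogis(0.2) + 1.5) ~ 0.53
  expect_error(generateCaptureHistories(50, 5, cmrModelSpec(), c(0, 1)),
               "expected 1 parameter")
})
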