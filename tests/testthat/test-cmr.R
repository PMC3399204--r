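eventsFixture <- function() {
  data.frame(
    id = c("f1", "f2", "f1", "f3", "f2", "f1"),
    occasion = c("jan", "jan", "feb", "feb", "mar", "jan"),
    mass = c(1.0, 1.5, 1.0, 0.8, 1.5, 1.0),
    stringsAsFactors = FALSE)
}

test_that("capture-event records assemble into the right detection matrix", {
  ch <- readCaptureEvents(eventsFixture())
  expect_equal(occasions(ch), c("jan", "feb", "mar"))
  expect_equal(nInd(ch), 3L)
  # within-occasion recaptures collapse: f1 appears twice in jan
  expect_equal(unname(detections(ch)["f1", ]), c(1L, 1L, 0L))
  expect_equal(unname(detections(ch)["f3", ]), c(0L, 1L, 0L))
  expect_equal(covariates(ch)$mass, c(1.0, 1.5, 0.8))
  expect_error(readCaptureEvents(eventsFixture(), idCol = "animal"),
               "missing column")
  expect_error(readCaptureEvents(eventsFixture(),
                                 occasionLevels = c("jan", "feb")),
               "unknown occasion")
  # file round-trip preserves the history
  f <- withr::local_tempfile()
  writeCaptureEvents(ch, f)
  back <- readCaptureEvents(f, occasionLevels = occasions(ch))
  expect_identical(detections(back), detections(ch))
  expect_equal(covariates(back)$mass, covariates(ch)$mass)
})

test_that("occasion pooling ORs detections and preserves capture totals", {
  ch <- readCaptureEvents(eventsFixture())
  pooled <- poolOccasions(ch, list(winter = c("jan", "feb")))
  expect_equal(occasions(pooled), c("winter", "mar"))
  expect_equal(unname(detections(pooled)["f1", ]), c(1L, 0L))
  # every animal keeps at least one detection
  expect_true(all(rowSums(detections(pooled)) >= 1))
  expect_error(poolOccasions(ch, list(a = "jan", b = "jan")),
               "more than one group")
  expect_error(poolOccasions(ch, list(a = "june")), "unknown occasion")
})

test_that("covariate normalization is the population z-score", {
  ch <- readCaptureEvents(data.frame(
    id = c("a", "b", "c"), occasion = c("o1", "o1", "o2"),
    mass = c(1, 2, 3)))
  n <- normalizeCovariates(ch)
  # denominator-n sd of (1,2,3) is sqrt(2/3)
  expect_equal(covariates(n)$mass, c(-1, 0, 1) / sqrt(2 / 3),
               tolerance = 1e-12)
  expect_equal(unname(n@scaling$mass), c(2, sqrt(2 / 3)), tolerance = 1e-12)
  chZ <- readCaptureEvents(data.frame(
    id = c("a", "b"), occasion = c("o1", "o2"), mass = c(1, 1)))
  expect_error(normalizeCovariates(chZ), "zero variance")
})

test_that("capture probabilities follow the linear predictor by hand", {
  m0 <- cmrModelSpec()
  expect_equal(captureProbability(m0, 0), 0.5)
  expect_equal(captureProbability(m0, qlogis(0.3)), 0.3, tolerance = 1e-12)
  mt <- cmrModelSpec(time = TRUE)
  expect_equal(captureProbability(mt, c(0, 1, -1), occasion = 2L, T = 3L),
               plogis(1))
  mb <- cmrModelSpec(behavior = TRUE)
  expect_equal(captureProbability(mb, c(0, -2), previouslyCaptured = TRUE),
               plogis(-2))
  expect_equal(captureProbability(mb, c(0, -2), previouslyCaptured = FALSE),
               0.5)
  mh <- cmrModelSpec(heterogeneity = "quadratic", covariate = "w")
  expect_equal(captureProbability(mh, c(0.5, 1, -0.5), covariate = 2),
               plogis(0.5 + 2 - 2), tolerance = 1e-12)
  expect_error(captureProbability(mt, c(0, 1), T = 3L), "expected 3")
})

test_that("the constant model matches a closed-form grid oracle", {
  sim <- generateCaptureHistories(100, 8, cmrModelSpec(), qlogis(0.2),
                                  seed = 42)
  fit <- fitHuggins(sim$history, cmrModelSpec())
  D <- nInd(sim$history)
  C <- sum(detections(sim$history))
  oracle <- m0GridMLE(D, 8, C)
  expect_equal(plogis(unname(coef(fit)[1])), oracle$pHat, tolerance = 1e-4)
  expect_equal(abundance(fit), oracle$Nhat, tolerance = 1e-3)
  expect_equal(logLik(fit), oracle$logLik, tolerance = 1e-6)
  expect_equal(AIC(fit), -2 * logLik(fit) + 2)
  expect_true(fit@converged)
})

test_that("likelihoods nest and ties break toward parsimony", {
  sim <- generateCaptureHistories(120, 6, cmrModelSpec(), qlogis(0.25),
                                  seed = 7)
  f0 <- fitHuggins(sim$history, cmrModelSpec())
  ft <- fitHuggins(sim$history, cmrModelSpec(time = TRUE))
  fb <- fitHuggins(sim$history, cmrModelSpec(behavior = TRUE))
  expect_gte(logLik(ft), logLik(f0) - 1e-6)
  expect_gte(logLik(fb), logLik(f0) - 1e-6)
  # force an exact AIC tie: the richer model must lose
  fbTie <- fb
  fbTie@AIC <- f0@AIC
  sel <- selectModel(list(fbTie, f0))
  expect_equal(modelLabel(modelSpec(sel)), "M(0)")
})

test_that("when every animal is caught the abundance estimate is D", {
  # capture probability ~1: all animals detected on most occasions
  sim <- generateCaptureHistories(30, 5, cmrModelSpec(), qlogis(0.999),
                                  seed = 3)
  fit <- fitHuggins(sim$history, cmrModelSpec())
  expect_equal(abundance(fit), nInd(sim$history), tolerance = 1e-3)
})

test_that("the model sweep covers the family and selection is sane", {
  spec <- cmrModelSpec(heterogeneity = "linear", covariate = "w")
  sim <- generateCaptureHistories(150, 8, spec, c(qlogis(0.3), 1),
                                  seed = 11)
  fits <- fitAllModels(sim$history, covariate = "w",
                       includeQuadratic = TRUE, seed = 2)
  expect_setequal(names(fits),
                  c("M(0)", "M(t)", "M(b)", "M(h)", "M(tb)", "M(th)",
                    "M(bh)", "M(tbh)", "M(h2)"))
  tab <- modelTable(fits)
  expect_equal(nrow(tab), 9L)
  expect_true(all(diff(tab$AIC[tab$converged]) >= -1e-9))
  best <- selectModel(fits)
  # the generating heterogeneity should beat the constant model
  expect_lt(AIC(fits[["M(h)"]]), AIC(fits[["M(0)"]]))
  expect_true(abundance(best) > nInd(sim$history))
  # without a covariate only the four non-heterogeneity models are fit
  fits4 <- fitAllModels(sim$history)
  expect_setequal(names(fits4), c("M(0)", "M(t)", "M(b)", "M(tb)"))
  expect_error(fitAllModels(sim$history, includeQuadratic = TRUE),
               "requires a covariate")
})

test_that("pooling occasions preserves the animal set for abundance", {
  spec <- cmrModelSpec()
  sim <- generateCaptureHistories(80, 9, spec, qlogis(0.15), seed = 9)
  ch <- sim$history
  pooled <- poolOccasions(ch, list(
    p1 = occasions(ch)[1:3], p2 = occasions(ch)[4:6],
    p3 = occasions(ch)[7:9]))
  expect_equal(nInd(pooled), nInd(ch))
  fit <- fitHuggins(pooled, spec)
  expect_true(fit@converged)
  # pooled occasions have higher per-occasion capture probability
  expect_gt(plogis(coef(fit)[[1]]), 0.15)
})
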