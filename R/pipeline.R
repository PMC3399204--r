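# End-to-end reporting layer: assembles the module outputs into the
# tab-separated tables a study report needs.  All randomized steps take
# explicit seeds, which are echoed in the output headers so any run can be
# reproduced exactly.

writeTsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Per-population diversity report
#'
#' Runs [populationSummary()] for every population, plus private-allele and
#' monomorphic-locus tabulations, and (optionally) writes tab-separated
#' outputs.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param g rarefaction gene count (default: minimum across all cells).
#' @param seed seed for the Hardy-Weinberg Monte-Carlo branch.
#' @param hweSteps Monte-Carlo steps for large Hardy-Weinberg tables.
#' @param outDir output directory; when NULL nothing is written.
#' @return list with \code{summary} (data.frame, one row per population),
#'   \code{privateAlleles} (named list) and \code{monomorphic} (named
#'   integer).
#' @export
diversityReport <- function(gm, g = NULL, seed = 1L, hweSteps = 20000L,
                            outDir = NULL) {
  pops <- unique(gm@populations)
  aft <- alleleFrequencies(gm)
  if (is.null(g)) g <- defaultRarefactionG(aft)
  rows <- lapply(pops, function(p)
    summaryRow(populationSummary(gm, p, g = g, seed = seed,
                                 hweSteps = hweSteps)))
  summary <- do.call(rbind, rows)
  priv <- lapply(pops, function(p)
    privateAlleles(aft, p, setdiff(pops, p)))
  names(priv) <- pops
  mono <- vapply(pops, function(p) countMonomorphicLoci(aft, p), integer(1))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTsv(summary, file.path(outDir, "diversity_summary.tsv"),
             sprintf("diversity summary | rarefaction g = %d | seed = %d",
                     g, seed))
    privDf <- do.call(rbind, lapply(pops, function(p) data.frame(
      population = p, locus = names(priv[[p]]),
      private = vapply(priv[[p]], paste, character(1), collapse = ","),
      stringsAsFactors = FALSE)))
    writeTsv(privDf, file.path(outDir, "private_alleles.tsv"),
             "private alleles per population and locus")
  }
  list(summary = summary, privateAlleles = priv, monomorphic = mono, g = g)
}

#' Pairwise F_ST matrix report
#'
#' @param gm a [GenotypeMatrix-class].
#' @param nBoot,nPerm,seed passed to [pairwiseFst()].
#' @param outDir optional output directory.
#' @return data.frame with one row per population pair (theta, CI, perm p).
#' @export
fstReport <- function(gm, nBoot = 1000L, nPerm = 1500L, seed = 1L,
                      outDir = NULL) {
  pops <- unique(gm@populations)
  if (length(pops) < 2) stop("need at least two populations")
  prs <- combn(pops, 2)
  rows <- lapply(seq_len(ncol(prs)), function(k) {
    r <- pairwiseFst(gm, prs[1, k], prs[2, k], nBoot = nBoot,
                     nPerm = nPerm, seed = seed + k)
    data.frame(popA = prs[1, k], popB = prs[2, k], theta = r@theta,
               ciLow = r@ciLow, ciHigh = r@ciHigh, permP = r@permP,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTsv(out, file.path(outDir, "pairwise_fst.tsv"),
             sprintf("pairwise F_ST | %d bootstraps, %d permutations, seed %d",
                     nBoot, nPerm, seed))
  }
  out
}

#' Capture-recapture report
#'
#' Runs both closure tests, fits the closed-population model family, selects
#' the minimum-AIC model, and scales the study-area abundance by an
#' area-expansion factor (e.g. 2 when the surveyed area holds about half the
#' population).
#'
#' @param ch a [CaptureHistory-class].
#' @param covariate covariate for the heterogeneity models (NA to skip).
#' @param includeQuadratic also fit quadratic M(h).
#' @param expansionFactor multiplier from study-area to total abundance.
#' @param seed fit seed.
#' @param outDir optional output directory.
#' @return list with \code{closure} (data.frame), \code{models}
#'   (data.frame), \code{selected} ([CMRFit-class]), \code{NhatStudyArea},
#'   \code{NhatTotal}.
#' @export
cmrReport <- function(ch, covariate = NA_character_, includeQuadratic = FALSE,
                      expansionFactor = 1, seed = 1L, outDir = NULL) {
  t1 <- closureTestStanleyBurnham(ch)
  t2 <- closureTestOtis(ch)
  closure <- data.frame(
    test = c(t1@test, t2@test), statistic = c(t1@statistic, t2@statistic),
    df = c(t1@df, t2@df), p = c(t1@p, t2@p),
    verdict = c(t1@verdict, t2@verdict), stringsAsFactors = FALSE)
  fits <- fitAllModels(ch, covariate = covariate,
                       includeQuadratic = includeQuadratic, seed = seed)
  models <- modelTable(fits)
  sel <- selectModel(fits)
  if (!is.na(t1@p) && !is.na(t2@p) && xor(t1@p < 0.05, t2@p < 0.05))
    message("closure tests disagree; closed-model estimates carry the ",
            "caveat that the population may be open")
  out <- list(closure = closure, models = models, selected = sel,
              NhatStudyArea = sel@Nhat,
              NhatTotal = sel@Nhat * expansionFactor)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTsv(closure, file.path(outDir, "closure_tests.tsv"),
             "population closure tests (low p suggests an open population)")
    writeTsv(models, file.path(outDir, "cmr_models.tsv"),
             sprintf("closed-population model sweep | seed %d | selected %s",
                     seed, modelLabel(sel@spec)))
  }
  out
}

#' Drift forecast and effective-size report
#'
#' Joins the closed-form estimators (effective size from heterozygosity
#' decline and from census size, effective inbreeding) with a Monte-Carlo
#' drift forecast from a calibrated initial frequency panel.
#'
#' @param H0 source-population heterozygosity.
#' @param Ht present island heterozygosity.
#' @param t generations since founding.
#' @param N census size estimate.
#' @param censusRatio \eqn{N_e/N} ratio.
#' @param HtargetIsland heterozygosity of the severely depauperate reference
#'   population used by [generationsToThreshold()] (NA to skip).
#' @param initFreqs initial frequency panel; default
#'   \code{calibratedFrequencies(meanHet = H0)}.
#' @param generations,replicates,seed drift simulation settings.
#' @param outDir optional output directory.
#' @return list with \code{neHetLoss}, \code{neCensus}, \code{FeIsland},
#'   \code{trajectory}, \code{generationsToTarget}.
#' @export
forecastReport <- function(H0, Ht, t, N, censusRatio = 0.1,
                           HtargetIsland = NA, initFreqs = NULL,
                           generations = 50L, replicates = 1000L, seed = 1L,
                           outDir = NULL) {
  neHet <- neFromHetLoss(H0, Ht, t)
  neCen <- neFromCensus(N, censusRatio)
  fe <- effectiveInbreeding(Ht, H0)
  if (is.null(initFreqs)) initFreqs <- calibratedFrequencies(meanHet = H0)
  traj <- simulateDrift(initFreqs, Ne = round(neCen$Ne),
                        generations = generations, replicates = replicates,
                        seed = seed)
  gens <- if (is.na(HtargetIsland)) NA_integer_
          else generationsToThreshold(traj, HtargetIsland)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    df <- data.frame(generation = traj@generations, meanHet = traj@meanHet,
                     hetLow = traj@hetLow, hetHigh = traj@hetHigh,
                     meanAlleles = traj@meanAlleles,
                     allelesLow = traj@allelesLow,
                     allelesHigh = traj@allelesHigh)
    writeTsv(df, file.path(outDir, "drift_forecast.tsv"),
             sprintf("drift forecast | Ne = %g | %d replicates | seed %d",
                     traj@Ne, replicates, seed))
    est <- data.frame(
      quantity = c("Ne_het_loss", "Ne_census", "Fe_island"),
      value = c(neHet$Ne, neCen$Ne, fe$Fe))
    writeTsv(est, file.path(outDir, "effective_size.tsv"),
             sprintf("closed-form estimators | H0 = %g, Ht = %g, t = %g, N = %g",
                     H0, Ht, t, N))
  }
  list(neHetLoss = neHet, neCensus = neCen, FeIsland = fe, trajectory = traj,
       generationsToTarget = gens)
}

#' Drift forecast plot
#'
#' Base-graphics chart of the simulated decline in mean heterozygosity and
#' mean allele number with 95\% envelopes.
#'
#' @param traj a [DriftTrajectory-class].
#' @param current optional named numeric \code{c(generation=, H=)} marking
#'   the present-day state.
#' @return invisibly, \code{traj}.
#' @importFrom graphics lines legend points par
#' @export
plotDriftForecast <- function(traj, current = NULL) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  g <- traj@generations
  plot(g, traj@meanHet, type = "l", ylim = c(0, max(traj@hetHigh)),
       xlab = "generation", ylab = "mean heterozygosity")
  lines(g, traj@hetLow, lty = 3); lines(g, traj@hetHigh, lty = 3)
  if (!is.null(current))
    points(current["generation"], current["H"], pch = 18, cex = 1.4)
  plot(g, traj@meanAlleles, type = "l",
       ylim = c(1, max(traj@allelesHigh)),
       xlab = "generation", ylab = "mean allele number")
  lines(g, traj@allelesLow, lty = 3); lines(g, traj@allelesHigh, lty = 3)
  invisible(traj)
}
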