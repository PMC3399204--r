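# Seed-deterministic generators with known truth, used to validate every
# stage of the pipeline.

#' Generate genotypes for one population at known allele frequencies
#'
#' Each individual's two genes at a locus are drawn from the population
#' frequencies; with inbreeding \code{fis > 0} the second gene copies the
#' first with probability \code{fis} (identity by descent) and is otherwise
#' an independent draw.
#'
#' @param popLabel population label.
#' @param n number of individuals (>= 1).
#' @param freqs named list of per-locus allele frequency vectors; names of
#'   each vector are integer allele labels.
#' @param fis within-population inbreeding coefficient in [0, 1).
#' @param missingRate per-call missing probability (default 0).
#' @param seed RNG seed.
#' @param idPrefix prefix for individual identifiers.
#' @return a [GenotypeMatrix-class].
#' @export
generateGenotypes <- function(popLabel, n, freqs, fis = 0, missingRate = 0,
                              seed = 1L, idPrefix = popLabel) {
  stopifnot(n >= 1, fis >= 0, fis < 1, missingRate >= 0, missingRate < 1)
  for (f in freqs)
    if (any(f < 0) || abs(sum(f) - 1) > 1e-9)
      stop("each locus frequency vector must be nonnegative and sum to 1")
  set.seed(seed)
  L <- length(freqs)
  lociNames <- if (is.null(names(freqs))) sprintf("L%02d", seq_len(L))
               else names(freqs)
  a <- matrix(NA_integer_, n, L)
  b <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    p <- freqs[[l]]
    al <- as.integer(names(p))
    if (any(is.na(al))) al <- seq_along(p)
    drawGenes <- function(n) {
      if (length(al) == 1) rep(al, n)
      else sample(al, n, replace = TRUE, prob = p)
    }
    g1 <- drawGenes(n)
    ibd <- runif(n) < fis
    g2 <- ifelse(ibd, g1, drawGenes(n))
    miss <- runif(n) < missingRate
    g1[miss] <- NA_integer_; g2[miss] <- NA_integer_
    a[, l] <- pmin(g1, g2); b[, l] <- pmax(g1, g2)
  }
  newGenotypeMatrix(sprintf("%s_%03d", idPrefix, seq_len(n)), lociNames,
                    rep(popLabel, n), a, b)
}

#' Combine per-population genotype matrices
#'
#' @param ... [GenotypeMatrix-class] objects sharing the same loci.
#' @return one [GenotypeMatrix-class].
#' @export
bindPopulations <- function(...) {
  gms <- list(...)
  stopifnot(length(gms) >= 1)
  lociRef <- gms[[1]]@loci
  for (g in gms)
    if (!identical(g@loci, lociRef)) stop("loci must match across matrices")
  newGenotypeMatrix(
    make.unique(unlist(lapply(gms, slot, "individuals"))), lociRef,
    unlist(lapply(gms, slot, "populations")),
    do.call(rbind, lapply(gms, slot, "alleleA")),
    do.call(rbind, lapply(gms, slot, "alleleB")))
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) { g <- numeric(length(alpha)); g[which.max(alpha)] <- 1 }
  g / sum(g)
}

#' Generate differentiated populations at a target F_ST
#'
#' Per population and locus, allele frequencies are drawn from a
#' Balding-Nichols Dirichlet distribution centred on the ancestral
#' frequencies with concentration \eqn{(1-F_{ST})/F_{ST}}, then genotypes are
#' sampled in Hardy-Weinberg proportions.  Provides generator truth for
#' differentiation estimators.
#'
#' @param ancestralFreqs named list of per-locus allele frequency vectors.
#' @param fst target differentiation in (0, 1).
#' @param popSizes named integer vector: individuals per population.
#' @param seed RNG seed.
#' @return a [GenotypeMatrix-class] containing all populations.
#' @export
generateStructuredPops <- function(ancestralFreqs, fst, popSizes, seed = 1L) {
  if (fst <= 0 || fst >= 1) stop("fst must lie in (0, 1)")
  if (is.null(names(popSizes)))
    names(popSizes) <- sprintf("pop%d", seq_along(popSizes))
  set.seed(seed)
  conc <- (1 - fst) / fst
  pieces <- vector("list", length(popSizes))
  for (k in seq_along(popSizes)) {
    drawn <- lapply(ancestralFreqs, function(p) {
      q <- rdirichlet1(p * conc)
      names(q) <- names(p)
      q
    })
    pieces[[k]] <- generateGenotypes(names(popSizes)[k], popSizes[k], drawn,
                                     seed = sample.int(2^31 - 1, 1),
                                     idPrefix = names(popSizes)[k])
  }
  do.call(bindPopulations, pieces)
}

# internal Wright-Fisher iteration on a frequency list
wfIterate <- function(freqs, Ne, generations) {
  twoNe <- 2L * as.integer(Ne)
  for (g in seq_len(generations)) {
    freqs <- lapply(freqs, function(p) {
      if (length(p) == 1) return(p)
      cnt <- rmultinom(1, twoNe, p)[, 1]
      keep <- cnt > 0
      setNames(cnt[keep] / twoNe, names(p)[keep])
    })
  }
  freqs
}

#' Simulate a founder bottleneck followed by drift
#'
#' Samples \code{2 * nFounders} genes per locus from the source frequencies
#' (founders' genes as a simple random sample, no family structure), runs
#' Wright-Fisher drift at constant \code{Ne} for the stated number of
#' generations, then draws a genotype sample from the resulting frequencies.
#' The defaults emulate an island population founded by at most 16
#' individuals that has drifted for about seven generations at a small
#' constant effective size.
#'
#' @param sourceFreqs named list of per-locus allele frequency vectors.
#' @param nFounders founding individuals (default 16).
#' @param Ne post-founding effective population size (default 11).
#' @param generations generations of drift (default 7).
#' @param sampleSize individuals in the final genotype sample (default 12).
#' @param popLabel label of the generated population.
#' @param seed RNG seed.
#' @return a [GenotypeMatrix-class].
#' @export
founderBottleneck <- function(sourceFreqs, nFounders = 16L, Ne = 11L,
                              generations = 7L, sampleSize = 12L,
                              popLabel = "island", seed = 1L) {
  stopifnot(nFounders >= 1, generations >= 0, sampleSize >= 1)
  set.seed(seed)
  founderFreqs <- lapply(sourceFreqs, function(p) {
    cnt <- rmultinom(1, 2L * as.integer(nFounders), p)[, 1]
    keep <- cnt > 0
    setNames(cnt[keep] / sum(cnt), names(p)[keep])
  })
  finalFreqs <- wfIterate(founderFreqs, Ne, generations)
  generateGenotypes(popLabel, sampleSize, finalFreqs,
                    seed = sample.int(2^31 - 1, 1))
}

#' Simulate capture histories under a known model
#'
#' Simulates detections of \code{Ntrue} animals over \code{T} occasions under
#' a closed-population capture-probability model, then discards animals never
#' detected (mirroring real trapping data, which only contain captured
#' animals).  The generating truth is returned alongside the history.
#'
#' @param Ntrue true population size.
#' @param T number of occasions.
#' @param spec a [CMRModelSpec-class].
#' @param params coefficient vector matching \code{spec} (see
#'   [captureProbability()] for the order).
#' @param covariateSampler function(n) drawing per-animal covariate values;
#'   default standard normal.
#' @param seed RNG seed.
#' @return list with \code{history} (a [CaptureHistory-class]) and
#'   \code{truth} (N, T, spec, params, covariates of all animals, detected
#'   flags).
#' @export
generateCaptureHistories <- function(Ntrue, T, spec, params,
                                     covariateSampler = function(n)
                                       rnorm(n),
                                     seed = 1L) {
  stopifnot(Ntrue >= 1, T >= 2)
  if (length(params) != nParams(spec, T))
    stop(sprintf("expected %d parameters for %s with T = %d",
                 nParams(spec, T), modelLabel(spec), T))
  set.seed(seed)
  w <- if (spec@heterogeneity != "none") covariateSampler(Ntrue)
       else numeric(Ntrue)
  sp <- splitParams(params, spec, T, w)
  y <- matrix(0L, Ntrue, T)
  caught <- rep(FALSE, Ntrue)
  for (j in seq_len(T)) {
    eta <- sp$b0 + sp$timeEff[j] + sp$bBehav * caught + sp$covEff
    y[, j] <- rbinom(Ntrue, 1, plogis(eta))
    caught <- caught | y[, j] == 1L
  }
  covName <- if (is.na(spec@covariate)) "w" else spec@covariate
  keep <- which(rowSums(y) > 0)
  ids <- sprintf("a%04d", keep)
  covs <- data.frame(w = w[keep], row.names = ids)
  names(covs) <- covName
  ch <- new("CaptureHistory", individuals = ids,
            occasions = sprintf("occ%02d", seq_len(T)),
            detections = matrix(y[keep, , drop = FALSE], length(keep), T,
                                dimnames = list(ids,
                                                sprintf("occ%02d",
                                                        seq_len(T)))),
            covariates = covs, scaling = list())
  list(history = ch,
       truth = list(N = Ntrue, T = T, spec = spec, params = params,
                    covariates = w, detected = seq_len(Ntrue) %in% keep))
}
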