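# Wright-Fisher drift: each generation the next gene pool is a multinomial
# draw of 2*Ne genes from current frequencies, independently per locus.
# Within the simulator heterozygosity is gene diversity 1 - sum(p^2) without
# a small-sample correction, for which the geometric decay
# H_t = H_0 (1 - 1/(2 Ne))^t holds exactly in expectation.

#' Closed-form heterozygosity decay under drift
#'
#' \eqn{H_t = H_0 \, (1 - 1/(2 N_e))^t}.
#'
#' @param H0 initial heterozygosity in [0, 1].
#' @param Ne effective population size (> 0.5; need not be integer).
#' @param t generations (>= 0; vectorized).
#' @return expected heterozygosity at generation \code{t}.
#' @examples
#' projectHeterozygosity(0.597, 10.14, 7)   # ~0.419
#' @export
projectHeterozygosity <- function(H0, Ne, t) {
  if (H0 < 0 || H0 > 1) stop("H0 must lie in [0, 1]")
  if (Ne <= 0.5) stop("Ne must exceed 0.5 (retention factor must be positive)")
  if (any(t < 0)) stop("t must be nonnegative")
  H0 * (1 - 1 / (2 * Ne))^t
}

#' Monte-Carlo Wright-Fisher drift simulation
#'
#' Simulates allele-frequency drift forward in time at independent loci for a
#' constant effective population size: per replicate, locus and generation,
#' \eqn{2 N_e} genes are drawn multinomially from the previous generation's
#' frequencies.  Records per generation the gene diversity
#' \eqn{1 - \sum_k p_k^2} and the surviving allele count, averaged over loci,
#' with empirical 2.5/97.5 percentile envelopes across replicates.
#'
#' @param initFreqs list of per-locus named numeric frequency vectors, each
#'   summing to 1 (see [calibratedFrequencies()] for a ready-made panel).
#' @param Ne effective population size (integer >= 1).
#' @param generations number of generations to simulate.
#' @param replicates Monte-Carlo replicates.
#' @param seed RNG seed.
#' @param keepReplicates retain the per-replicate mean-heterozygosity matrix.
#' @return a [DriftTrajectory-class]; generation 0 is the initial state.
#' @export
simulateDrift <- function(initFreqs, Ne, generations = 50L,
                          replicates = 1000L, seed = 1L,
                          keepReplicates = FALSE) {
  stopifnot(is.list(initFreqs), length(initFreqs) >= 1)
  for (f in initFreqs) {
    if (any(f < 0) || abs(sum(f) - 1) > 1e-9)
      stop("each locus frequency vector must be nonnegative and sum to 1")
  }
  Ne <- as.integer(round(Ne))
  if (Ne < 1) stop("Ne must be >= 1")
  G <- as.integer(generations)
  R <- as.integer(replicates)
  set.seed(seed)
  L <- length(initFreqs)
  twoNe <- 2L * Ne
  hetRep <- matrix(NA_real_, R, G + 1L)
  allRep <- matrix(NA_real_, R, G + 1L)
  h0 <- mean(vapply(initFreqs, function(p) 1 - sum(p^2), numeric(1)))
  a0 <- mean(vapply(initFreqs, function(p) sum(p > 0), numeric(1)))
  for (r in seq_len(R)) {
    freqs <- initFreqs
    hetRep[r, 1] <- h0
    allRep[r, 1] <- a0
    for (g in seq_len(G)) {
      het <- numeric(L); nal <- numeric(L)
      for (l in seq_len(L)) {
        p <- freqs[[l]]
        if (length(p) > 1) {
          cnt <- rmultinom(1, twoNe, p)[, 1]
          keep <- cnt > 0
          p <- cnt[keep] / twoNe
          freqs[[l]] <- p
        }
        het[l] <- 1 - sum(p^2)
        nal[l] <- length(p)
      }
      hetRep[r, g + 1L] <- mean(het)
      allRep[r, g + 1L] <- mean(nal)
    }
  }
  env <- function(m) apply(m, 2, quantile, probs = c(0.025, 0.975),
                           names = FALSE)
  he <- env(hetRep); ae <- env(allRep)
  new("DriftTrajectory",
      generations = 0:G,
      meanHet = colMeans(hetRep), hetLow = he[1, ], hetHigh = he[2, ],
      meanAlleles = colMeans(allRep), allelesLow = ae[1, ],
      allelesHigh = ae[2, ],
      replicateHet = if (keepReplicates) hetRep else
        matrix(numeric(0), 0, 0),
      Ne = as.numeric(Ne), replicates = R, seed = as.integer(seed))
}

#' First generation at which mean heterozygosity falls to a target
#'
#' @param traj a [DriftTrajectory-class].
#' @param targetH target mean heterozygosity.
#' @return smallest generation with mean simulated heterozygosity at or below
#'   \code{targetH}; 0 if already at or below it initially; NA if never
#'   reached within the simulated horizon.
#' @export
generationsToThreshold <- function(traj, targetH) {
  if (targetH >= traj@meanHet[1]) return(0L)
  hit <- which(traj@meanHet <= targetH)
  if (!length(hit)) return(NA_integer_)
  traj@generations[hit[1]]
}

#' A calibrated multilocus initial frequency panel
#'
#' Builds a deterministic set of per-locus allele frequencies with a given
#' number of alleles per locus and a given mean gene diversity, for use as
#' the starting state of drift forecasts when real frequencies are not
#' available.  Per locus the frequencies follow a geometric profile
#' \eqn{p_j \propto \lambda^{j-1}}; a single decay \eqn{\lambda} shared by
#' all loci is solved so the across-locus mean of \eqn{1-\sum p^2} equals
#' \code{meanHet}.
#'
#' @param allelesPerLocus integer vector of allele counts, one per locus.
#'   The default mirrors a 13-locus microsatellite panel averaging 9 alleles
#'   per locus with one monomorphic locus.
#' @param meanHet target mean gene diversity (default 0.597).
#' @return named list of per-locus frequency vectors.
#' @export
calibratedFrequencies <- function(
    allelesPerLocus = c(10L, 6L, 6L, 4L, 18L, 12L, 3L, 1L, 9L, 14L, 8L,
                        10L, 16L),
    meanHet = 0.597) {
  lociNames <- sprintf("L%02d", seq_along(allelesPerLocus))
  profile <- function(k, lambda) {
    if (k == 1) return(1)
    p <- lambda^(0:(k - 1))
    p / sum(p)
  }
  meanH <- function(lambda)
    mean(vapply(allelesPerLocus,
                function(k) 1 - sum(profile(k, lambda)^2), numeric(1)))
  if (meanH(1) < meanHet)
    stop("target mean heterozygosity unattainable with this allele panel")
  lambda <- uniroot(function(l) meanH(l) - meanHet,
                    c(1e-6, 1), tol = 1e-12)$root
  out <- lapply(allelesPerLocus, function(k) {
    p <- profile(k, lambda)
    setNames(p, seq_len(k))
  })
  setNames(out, lociNames)
}
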