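# Closed-form effective-population-size and effective-inbreeding estimators.

#' Effective population size from heterozygosity decline
#'
#' Exact inversion of the drift decay \eqn{H_t = H_0 (1 - 1/(2N_e))^t}:
#' \deqn{N_e = \frac{1}{2\left[1 - (H_t/H_0)^{1/t}\right]}.}
#'
#' @param H0 initial heterozygosity (0 < Ht < H0 <= 1).
#' @param Ht heterozygosity after \code{t} generations.
#' @param t generations elapsed (>= 1).
#' @return list with \code{method = "het_loss"}, \code{Ne}, and the inputs.
#' @examples
#' neFromHetLoss(0.597, 0.419, 7)$Ne   # ~10.14
#' @export
neFromHetLoss <- function(H0, Ht, t) {
  if (Ht <= 0) stop("Ht must be positive")
  if (H0 > 1 || H0 <= 0) stop("H0 must lie in (0, 1]")
  if (Ht >= H0) stop("no diversity loss (Ht >= H0); Ne is unbounded")
  if (t < 1) stop("t must be >= 1")
  Ne <- 1 / (2 * (1 - (Ht / H0)^(1 / t)))
  list(method = "het_loss", Ne = Ne, H0 = H0, Ht = Ht, t = t)
}

#' Effective population size from census size
#'
#' \eqn{N_e = \mathrm{ratio} \times N}, with the widely used default ratio
#' \eqn{N_e/N = 0.1} for wild vertebrate populations.
#'
#' @param N census population size (>= 0).
#' @param ratio \eqn{N_e/N} in (0, 1].
#' @return list with \code{method = "census_ratio"}, \code{Ne}, and inputs.
#' @examples
#' neFromCensus(110)$Ne   # 11
#' @export
neFromCensus <- function(N, ratio = 0.1) {
  if (N < 0) stop("N must be nonnegative")
  if (ratio <= 0 || ratio > 1) stop("ratio must lie in (0, 1]")
  list(method = "census_ratio", Ne = ratio * N, N = N, ratio = ratio)
}

#' Effective inbreeding coefficient of an island population
#'
#' \eqn{F_e = 1 - H_{island}/H_{mainland}}: the cumulative inbreeding implied
#' by the island's heterozygosity deficit relative to its source population.
#'
#' @param Hisland island heterozygosity in [0, 1].
#' @param Hmainland mainland (source) heterozygosity in (0, 1].
#' @return list with \code{Fe}, \code{Hisland}, \code{Hmainland}.  A negative
#'   \code{Fe} (island more diverse than mainland) is returned with a
#'   warning.
#' @examples
#' effectiveInbreeding(0.419, 0.597)$Fe  # ~0.30
#' effectiveInbreeding(0.032, 0.597)$Fe  # ~0.95
#' @export
effectiveInbreeding <- function(Hisland, Hmainland) {
  if (Hmainland <= 0) stop("mainland heterozygosity must be positive")
  if (Hisland < 0 || Hisland > 1 || Hmainland > 1)
    stop("heterozygosities must lie in [0, 1]")
  Fe <- 1 - Hisland / Hmainland
  if (Fe < 0)
    warning("island heterozygosity exceeds mainland; Fe is negative")
  list(Fe = Fe, Hisland = Hisland, Hmainland = Hmainland)
}
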