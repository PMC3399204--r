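# Tests of the closed-population assumption.  Both tests take closure as the
# null hypothesis, so small p-values indicate the population is open.

# pmf of the range (last - first) of a uniform random k-subset of {1..T}
rangePmf <- function(k, T) {
  d <- (k - 1):(T - 1)
  p <- exp(log(T - d) + lchoose(d - 1, k - 2) - lchoose(T, k))
  list(d = d, p = p / sum(p))
}

#' Closure test based on capture ranges (Test 2)
#'
#' The classic closed-population test built from the spread between first and
#' last capture of each multiply-captured animal.  Conditional on an animal's
#' number of captures \eqn{k_i}, closure implies its capture occasions are a
#' uniform random subset of the \eqn{T} occasions, so the range
#' \eqn{l_i - f_i} has a known distribution.  Mortality truncates last
#' captures and recruitment delays first captures, both shrinking ranges, so
#' the standardized sum of ranges is referred to the lower normal tail:
#' \eqn{p = \Phi(z)}.
#'
#' @param ch a [CaptureHistory-class].
#' @return a [ClosureResult-class]; statistic NA when no animal was captured
#'   at least twice.
#' @export
closureTestOtis <- function(ch) {
  y <- ch@detections
  T <- ncol(y)
  if (T < 3) stop("closure test requires at least 3 occasions")
  kcap <- rowSums(y)
  multi <- which(kcap >= 2)
  if (!length(multi))
    return(new("ClosureResult", test = "Capture-range closure test (Test 2)",
               statistic = NA_real_, df = NA_real_, p = NA_real_,
               verdict = "no multiply-captured animals; test not applicable"))
  occ <- seq_len(T)
  dObs <- 0; eSum <- 0; vSum <- 0
  for (i in multi) {
    caught <- occ[y[i, ] == 1]
    dObs <- dObs + (max(caught) - min(caught))
    pmf <- rangePmf(kcap[i], T)
    mu <- sum(pmf$d * pmf$p)
    eSum <- eSum + mu
    vSum <- vSum + sum((pmf$d - mu)^2 * pmf$p)
  }
  if (vSum <= 0)
    return(new("ClosureResult", test = "Capture-range closure test (Test 2)",
               statistic = NA_real_, df = NA_real_, p = NA_real_,
               verdict = "degenerate: capture ranges carry no information"))
  z <- (dObs - eSum) / sqrt(vSum)
  p <- pnorm(z)
  new("ClosureResult", test = "Capture-range closure test (Test 2)",
      statistic = z, df = NA_real_, p = p,
      verdict = if (p < 0.05) "evidence against closure (short capture ranges)"
                else "no evidence against closure")
}

pearson2x2 <- function(tb) {
  # returns chi-square or NA when a margin is zero
  if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) return(NA_real_)
  E <- outer(rowSums(tb), colSums(tb)) / sum(tb)
  sum((tb - E)^2 / E)
}

#' Contingency-table closure test (Test 1)
#'
#' A chi-square closure test combining, for every interior occasion \eqn{i},
#' two 2x2 independence components: a mortality/emigration component over
#' animals already marked before \eqn{i} (captured at \eqn{i} versus captured
#' after \eqn{i}), and a recruitment component over animals seen after
#' \eqn{i} (captured at \eqn{i} versus captured before \eqn{i}).  Under
#' closure each table satisfies independence; permanent departures or
#' arrivals induce association.  Components with a zero margin are dropped
#' and the degrees of freedom adjusted accordingly.
#'
#' @param ch a [CaptureHistory-class].
#' @return a [ClosureResult-class].
#' @export
closureTestStanleyBurnham <- function(ch) {
  y <- ch@detections
  T <- ncol(y)
  if (T < 4) stop("closure test requires at least 4 occasions")
  stat <- 0; df <- 0L; dropped <- 0L
  for (i in 2:(T - 1)) {
    before <- rowSums(y[, seq_len(i - 1), drop = FALSE]) > 0
    after <- rowSums(y[, (i + 1):T, drop = FALSE]) > 0
    at <- y[, i] == 1
    # mortality/emigration: among animals marked before i
    sel <- before
    if (sum(sel) >= 2) {
      tb <- table(factor(at[sel], c(FALSE, TRUE)),
                  factor(after[sel], c(FALSE, TRUE)))
      x2 <- pearson2x2(tb)
      if (!is.na(x2)) { stat <- stat + x2; df <- df + 1L }
      else dropped <- dropped + 1L
    }
    # recruitment: among animals seen after i
    sel <- after
    if (sum(sel) >= 2) {
      tb <- table(factor(at[sel], c(FALSE, TRUE)),
                  factor(before[sel], c(FALSE, TRUE)))
      x2 <- pearson2x2(tb)
      if (!is.na(x2)) { stat <- stat + x2; df <- df + 1L }
      else dropped <- dropped + 1L
    }
  }
  if (df == 0L)
    return(new("ClosureResult",
               test = "Contingency-table closure test (Test 1)",
               statistic = NA_real_, df = NA_real_, p = NA_real_,
               verdict = "no informative component tables"))
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  note <- if (dropped > 0)
    sprintf(" (%d degenerate component(s) dropped)", dropped) else ""
  new("ClosureResult", test = "Contingency-table closure test (Test 1)",
      statistic = stat, df = as.numeric(df), p = p,
      verdict = paste0(
        if (p < 0.05) "evidence against closure" else
          "no evidence against closure", note))
}
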