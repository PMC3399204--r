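# Exact conditional test of Hardy-Weinberg proportions given allele counts.
# P of a genotype array {n_ij} conditional on allele counts {m_i}:
#   P = n! (prod_i m_i!) 2^H / ((2n)! prod_{i<=j} n_ij!)
# with H the number of heterozygous individuals.  The p-value is the total
# probability of arrays no more probable than the observed one.

genotypeCountsAt <- function(gm, population, locus) {
  pi <- gm@populations == population
  if (!any(pi)) stop("unknown population label: ", population)
  l <- match(locus, gm@loci)
  if (is.na(l)) stop("unknown locus: ", locus)
  a <- gm@alleleA[pi, l]; b <- gm@alleleB[pi, l]
  ok <- !is.na(a)
  cbind(a = a[ok], b = b[ok])
}

# Enumerate all genotype arrays compatible with allele margins m, calling
# visit(nij, H) with the vector of pair counts (order: (1,1),(1,2),..,(k,k))
# and the heterozygote total.  Aborts returning -1 once more than `cap`
# arrays have been visited; otherwise returns the array count.
enumerateArrays <- function(m, visit, cap = Inf) {
  k <- length(m)
  pairI <- integer(0); pairJ <- integer(0)
  for (i in seq_len(k)) for (j in i:k) {
    pairI <- c(pairI, i); pairJ <- c(pairJ, j)
  }
  P <- length(pairI)
  hetMask <- pairI != pairJ
  lastOfRow <- c(pairI[-1] != pairI[-P], TRUE)
  nij <- integer(P)
  count <- 0L
  rec <- function(idx, rem) {
    if (count < 0L) return(invisible())
    if (idx > P) {
      count <<- count + 1L
      if (count > cap) { count <<- -1L; return(invisible()) }
      visit(nij, sum(nij[hetMask]))
      return(invisible())
    }
    i <- pairI[idx]; j <- pairJ[idx]
    if (i == j) {
      hi <- rem[i] %/% 2L
      lo <- if (lastOfRow[idx]) hi else 0L
      if (lastOfRow[idx] && rem[i] %% 2L != 0L) return(invisible())
      for (v in lo:hi) {
        nij[idx] <<- v
        rem2 <- rem; rem2[i] <- rem2[i] - 2L * v
        rec(idx + 1L, rem2)
        if (count < 0L) break
      }
    } else {
      hi <- min(rem[i], rem[j])
      lo <- if (lastOfRow[idx]) rem[i] else 0L
      if (lo > hi) { nij[idx] <<- 0L; return(invisible()) }
      for (v in lo:hi) {
        nij[idx] <<- v
        rem2 <- rem; rem2[i] <- rem2[i] - v; rem2[j] <- rem2[j] - v
        rec(idx + 1L, rem2)
        if (count < 0L) break
      }
    }
    nij[idx] <<- 0L
    invisible()
  }
  rec(1L, as.integer(m))
  count
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test given allele counts.  When complete enumeration of
#' the genotype arrays compatible with the allele counts is feasible (at most
#' \code{maxTables} arrays), the p-value sums the probability of all arrays
#' no more probable than the observed one.  Otherwise a Monte-Carlo version
#' repeatedly shuffles the observed gene pool into random diploid pairings
#' and applies the add-one tail estimator, so \eqn{p \in (0, 1]}.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param population population label.
#' @param locus locus name.
#' @param nSteps Monte-Carlo steps when enumeration is infeasible.
#' @param seed RNG seed for the Monte-Carlo branch.
#' @param maxTables enumeration ceiling (number of arrays, default 1e6).
#' @return p-value; NA for a monomorphic locus.
#' @export
hweExactTest <- function(gm, population, locus, nSteps = 100000L, seed = 1L,
                         maxTables = 1e6) {
  calls <- genotypeCountsAt(gm, population, locus)
  if (!nrow(calls)) return(NA_real_)
  genes <- c(calls[, 1], calls[, 2])
  lev <- sort(unique(genes))
  k <- length(lev)
  if (k < 2) return(NA_real_)
  m <- as.integer(table(factor(genes, levels = lev)))
  n <- nrow(calls)
  baseConst <- lfactorial(n) + sum(lfactorial(m)) - lfactorial(2 * n)

  # observed array in pair order (1,1),(1,2),...,(k,k)
  ii <- match(pmin(calls[, 1], calls[, 2]), lev)
  jj <- match(pmax(calls[, 1], calls[, 2]), lev)
  pairIdx <- function(i, j)
    (i - 1L) * (k + 1L) - (i * (i - 1L)) %/% 2L + j - i + 1L
  P <- (k * (k + 1L)) %/% 2L
  obs <- tabulate(pairIdx(ii, jj), nbins = P)
  logPObs <- baseConst + sum(ii != jj) * log(2) - sum(lfactorial(obs))
  tol <- 1e-9 * abs(logPObs) + 1e-12

  # enumeration is attempted only where it can plausibly fit the budget;
  # otherwise go straight to Monte-Carlo
  tryEnum <- k <= 3 || (k <= 6 && 2 * n <= 30)
  if (tryEnum) {
    pmass <- 0
    cnt <- enumerateArrays(m, function(nij, H) {
      lp <- baseConst + H * log(2) - sum(lfactorial(nij))
      if (lp <= logPObs + tol) pmass <<- pmass + exp(lp)
    }, cap = maxTables)
    if (cnt > 0) return(min(1, pmass))
  }

  # Monte-Carlo: shuffle the gene pool, pair consecutive genes
  set.seed(seed)
  idx <- match(genes, lev)
  hits <- 0L
  log2v <- log(2)
  for (s in seq_len(nSteps)) {
    perm <- sample(idx)
    i <- pmin(perm[seq_len(n)], perm[n + seq_len(n)])
    j <- pmax(perm[seq_len(n)], perm[n + seq_len(n)])
    cntv <- tabulate(pairIdx(i, j), nbins = P)
    lp <- baseConst + sum(i != j) * log2v - sum(lfactorial(cntv))
    if (lp <= logPObs + tol) hits <- hits + 1L
  }
  (hits + 1) / (nSteps + 1)
}
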