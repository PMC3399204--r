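# Per-population diversity statistics and Weir-Cockerham F-statistics.
# All statistics exclude missing calls locus-wise and are invariant to
# individual order and allele relabeling.

lociWithData <- function(gm, population) {
  pi <- gm@populations == population
  which(colSums(!is.na(gm@alleleA[pi, , drop = FALSE])) > 0)
}

#' Observed heterozygosity
#'
#' Per locus, the fraction of non-missing genotypes that are heterozygous,
#' and the mean over loci with data.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param population population label.
#' @return list with \code{perLocus} (named, NA where no data) and
#'   \code{mean}.
#' @export
observedHeterozygosity <- function(gm, population) {
  pi <- gm@populations == population
  if (!any(pi)) stop("unknown population label: ", population)
  a <- gm@alleleA[pi, , drop = FALSE]
  b <- gm@alleleB[pi, , drop = FALSE]
  het <- colSums(a != b, na.rm = TRUE)
  tot <- colSums(!is.na(a))
  per <- ifelse(tot > 0, het / tot, NA_real_)
  names(per) <- gm@loci
  list(perLocus = per, mean = mean(per[tot > 0]))
}

#' Unbiased expected heterozygosity (gene diversity)
#'
#' Per locus, Nei's unbiased estimator
#' \eqn{H_E = \frac{2n}{2n-1}\left(1 - \sum_k p_k^2\right)} with \eqn{n} the
#' number of non-missing genotypes, and the mean over retained loci.  Loci
#' with a single genotype are excluded with a warning.
#'
#' @inheritParams observedHeterozygosity
#' @return list with \code{perLocus} and \code{mean}.
#' @export
expectedHeterozygosity <- function(gm, population) {
  pi <- gm@populations == population
  if (!any(pi)) stop("unknown population label: ", population)
  per <- rep(NA_real_, nLoci(gm))
  names(per) <- gm@loci
  dropped <- character(0)
  for (l in seq_len(nLoci(gm))) {
    genes <- c(gm@alleleA[pi, l], gm@alleleB[pi, l])
    genes <- genes[!is.na(genes)]
    n <- length(genes) / 2
    if (n == 0) next
    if (n < 2) { dropped <- c(dropped, gm@loci[l]); next }
    p <- table(genes) / length(genes)
    per[l] <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
  }
  if (length(dropped))
    warning("loci with a single genotype excluded: ",
            paste(dropped, collapse = ", "))
  list(perLocus = per, mean = mean(per, na.rm = TRUE))
}

#' Rarefied allelic richness
#'
#' The expected number of distinct alleles in a random subsample of \code{g}
#' genes, per locus:
#' \eqn{r_g = \sum_k \left[1 - \binom{2N-N_k}{g}\big/\binom{2N}{g}\right]},
#' where \eqn{N_k} is the gene count of allele \eqn{k}.  When \code{g} is
#' omitted it defaults to the smallest gene count across all population x
#' locus cells with data in \code{gm} (the usual convention when several
#' populations are compared).
#'
#' @inheritParams observedHeterozygosity
#' @param g rarefaction gene count (even integer >= 2).
#' @return list with \code{perLocus}, \code{mean} and the \code{g} used.
#' @export
allelicRichness <- function(gm, population, g = NULL) {
  pi <- gm@populations == population
  if (!any(pi)) stop("unknown population label: ", population)
  aft <- alleleFrequencies(gm)
  if (is.null(g)) g <- defaultRarefactionG(aft)
  if (g < 2) stop("rarefaction gene count g must be >= 2")
  gc <- setNames(aft@geneCounts[population, ], colnames(aft@geneCounts))
  bad <- which(gc > 0 & gc < g)
  if (length(bad))
    stop("rarefaction size g = ", g, " exceeds the gene count at locus ",
         names(bad)[1])
  t <- aft@tab
  per <- rep(NA_real_, nLoci(gm))
  names(per) <- gm@loci
  for (l in gm@loci) {
    if (gc[l] == 0) next
    cnt <- t$count[t$population == population & t$locus == l]
    per[l] <- sum(1 - exp(lchoose(gc[l] - cnt, g) - lchoose(gc[l], g)))
  }
  list(perLocus = per, mean = mean(per, na.rm = TRUE), g = g)
}

#' Default rarefaction size
#'
#' The smallest gene count over all population x locus cells with data.
#'
#' @param aft an [AlleleFreqTable-class].
#' @return even integer gene count.
#' @export
defaultRarefactionG <- function(aft) {
  gc <- aft@geneCounts
  min(gc[gc > 0])
}

# Weir-Cockerham variance components per locus.  Returns one row per
# locus x allele with components a (between populations), b (between
# individuals within populations), c (within individuals).  With a single
# population only b and c are defined (a = NA).
wcComponents <- function(gm, pops) {
  r <- length(pops)
  out <- list()
  for (l in seq_len(nLoci(gm))) {
    ni <- numeric(r)
    freqs <- list()
    hets <- list()
    alleles <- integer(0)
    for (k in seq_len(r)) {
      pi <- gm@populations == pops[k]
      a <- gm@alleleA[pi, l]; b <- gm@alleleB[pi, l]
      ok <- !is.na(a)
      a <- a[ok]; b <- b[ok]
      ni[k] <- length(a)
      if (!ni[k]) { freqs[[k]] <- numeric(0); hets[[k]] <- numeric(0); next }
      genes <- c(a, b)
      cnt <- table(genes)
      freqs[[k]] <- setNames(as.numeric(cnt) / length(genes), names(cnt))
      alleles <- union(alleles, as.integer(names(cnt)))
      hetA <- vapply(as.integer(names(cnt)), function(al)
        sum((a == al) != (b == al)) / ni[k], numeric(1))
      hets[[k]] <- setNames(hetA, names(cnt))
    }
    use <- ni > 0
    if (sum(use) == 0 || length(alleles) < 2) next
    nu <- ni[use]; ru <- sum(use)
    nbar <- mean(nu)
    nsum <- sum(nu)
    nc <- if (ru > 1) (nsum - sum(nu^2) / nsum) / (ru - 1) else NA_real_
    for (al in sort(alleles)) {
      p <- vapply(which(use), function(k) {
        f <- freqs[[k]][as.character(al)]
        if (is.na(f)) 0 else f
      }, numeric(1))
      h <- vapply(which(use), function(k) {
        f <- hets[[k]][as.character(al)]
        if (is.na(f)) 0 else f
      }, numeric(1))
      pbar <- sum(nu * p) / nsum
      hbar <- sum(nu * h) / nsum
      s2 <- if (ru > 1) sum(nu * (p - pbar)^2) / ((ru - 1) * nbar) else 0
      inner <- pbar * (1 - pbar) - (ru - 1) / ru * s2
      aComp <- if (ru > 1)
        (nbar / nc) * (s2 - (inner - hbar / 4) / (nbar - 1))
      else NA_real_
      bComp <- (nbar / (nbar - 1)) *
        (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
      cComp <- hbar / 2
      out[[length(out) + 1L]] <- data.frame(
        locus = gm@loci[l], allele = al,
        a = aComp, b = bComp, c = cComp, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(locus = character(0), allele = integer(0),
                      a = numeric(0), b = numeric(0), c = numeric(0)))
  do.call(rbind, out)
}

#' Weir-Cockerham F-statistics
#'
#' Variance-components estimators of \eqn{F_{IS}}, \eqn{F_{ST}} and
#' \eqn{F_{IT}}.  Multilocus values combine loci as the ratio of summed
#' components ("ratio of averages").  Loci monomorphic over all requested
#' populations are excluded.  With a single population only \eqn{F_{IS}} is
#' defined.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param pops populations to include (default: all).
#' @return list with \code{FIS}, \code{FST}, \code{FIT} (multilocus) and a
#'   per-locus data.frame \code{perLocus}.
#' @export
wcFstats <- function(gm, pops = NULL) {
  if (is.null(pops)) pops <- unique(gm@populations)
  unknown <- setdiff(pops, unique(gm@populations))
  if (length(unknown))
    stop("unknown population label(s): ", paste(unknown, collapse = ", "))
  comp <- wcComponents(gm, pops)
  if (!nrow(comp))
    stop("all loci are monomorphic across the requested populations; ",
         "F-statistics are undefined")
  multi <- length(pops) > 1
  sumBy <- function(v) tapply(v, comp$locus, sum)
  perLocus <- data.frame(
    locus = names(sumBy(comp$c)),
    stringsAsFactors = FALSE)
  bS <- sumBy(comp$b); cS <- sumBy(comp$c)
  if (multi) {
    aS <- sumBy(comp$a)
    tot <- aS + bS + cS
    perLocus$FST <- as.numeric(aS / tot)
    perLocus$FIT <- as.numeric(1 - cS / tot)
  }
  perLocus$FIS <- as.numeric(1 - cS / (bS + cS))
  rownames(perLocus) <- NULL
  res <- list(
    FIS = 1 - sum(comp$c) / sum(comp$b + comp$c),
    FST = if (multi) sum(comp$a) / sum(comp$a + comp$b + comp$c) else NA_real_,
    FIT = if (multi) 1 - sum(comp$c) / sum(comp$a + comp$b + comp$c)
          else NA_real_,
    perLocus = perLocus)
  res
}

#' Pairwise (or global) F_ST with bootstrap CI and permutation test
#'
#' The multilocus Weir-Cockerham estimate for two populations, a 95\%
#' confidence interval from bootstrap resampling of loci, and a one-sided
#' permutation p-value obtained by randomly reassigning individuals to the
#' two populations, \eqn{p = (\#\{\theta^* \ge \theta\} + 1)/(n_{perm}+1)}.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param popA,popB the two population labels.
#' @param nBoot bootstrap replicates over loci (default 1000).
#' @param nPerm permutation replicates (default 1500).
#' @param seed RNG seed.
#' @return an [FstResult-class].
#' @export
pairwiseFst <- function(gm, popA, popB, nBoot = 1000L, nPerm = 1500L,
                        seed = 1L) {
  sub <- subsetPopulations(gm, c(popA, popB))
  # duplicated-label comparison: split one population in half
  if (popA == popB) {
    half <- seq_len(nInd(sub)) <= nInd(sub) / 2
    sub@populations <- ifelse(half, paste0(popA, ".1"), paste0(popA, ".2"))
    popA <- paste0(popA, ".1"); popB <- paste0(popB, ".2")
  }
  if (sum(sub@populations == popA) < 2 || sum(sub@populations == popB) < 2)
    stop("both populations need at least 2 individuals")
  comp <- wcComponents(sub, c(popA, popB))
  if (!nrow(comp)) stop("no polymorphic loci between ", popA, " and ", popB)
  theta <- sum(comp$a) / sum(comp$a + comp$b + comp$c)
  lociHere <- unique(comp$locus)
  set.seed(seed)
  if (length(lociHere) < 2) {
    warning("fewer than 2 polymorphic loci; CI is degenerate")
    ci <- c(theta, theta)
  } else {
    thetaBoot <- replicate(nBoot, {
      pick <- sample(lociHere, replace = TRUE)
      rows <- unlist(lapply(pick, function(l) which(comp$locus == l)))
      sum(comp$a[rows]) / sum(comp$a[rows] + comp$b[rows] + comp$c[rows])
    })
    ci <- quantile(thetaBoot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  labs <- sub@populations
  thetaPerm <- replicate(nPerm, {
    perm <- sub
    perm@populations <- sample(labs)
    cp <- wcComponents(perm, c(popA, popB))
    if (!nrow(cp)) return(NA_real_)
    sum(cp$a) / sum(cp$a + cp$b + cp$c)
  })
  permP <- (sum(thetaPerm >= theta - 1e-12, na.rm = TRUE) + 1) /
    (sum(!is.na(thetaPerm)) + 1)
  new("FstResult", pair = c(popA, popB), theta = theta,
      ciLow = ci[1], ciHigh = ci[2], permP = permP,
      nPerm = as.integer(nPerm), nBoot = as.integer(nBoot))
}

setMethod("show", "FstResult", function(object) {
  cat(sprintf(
    "F_ST (%s): theta = %.3f, 95%% CI [%.3f, %.3f], perm p = %.4g (%d perms)\n",
    paste(object@pair, collapse = " vs "), object@theta,
    object@ciLow, object@ciHigh, object@permP, object@nPerm))
})

#' Paired Wilcoxon signed-rank comparison of per-locus richness
#'
#' Exact two-sided signed-rank test for paired per-locus statistics (e.g.
#' allelic richness of two populations over the same loci).  Zero differences
#' are dropped; for up to 20 informative pairs the null distribution is
#' enumerated over all \eqn{2^m} sign patterns (tie-robust, using average
#' ranks), otherwise a normal approximation with tie correction is used.
#'
#' @param x,y equal-length paired numeric vectors.
#' @return two-sided p-value, or NA when no pair is informative.
#' @export
wilcoxonRichness <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  m <- length(d)
  if (m == 0) return(NA_real_)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  mu <- sum(rk) / 2
  if (m <= 20) {
    sums <- 0
    for (r in rk) sums <- c(sums, sums + r)
    p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
  } else {
    ties <- table(rk)
    sigma2 <- sum(rk^2) / 4
    z <- (W - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
  }
  min(1, p)
}

#' Assemble a population's diversity summary
#'
#' Computes the standard per-population summary row: sample size, mean
#' alleles per locus, rarefied allelic richness, observed and unbiased
#' expected heterozygosity, multilocus Weir-Cockerham \eqn{F_{IS}}, a
#' Fisher-combined Hardy-Weinberg exact p-value over polymorphic loci, the
#' rare-allele summary, and the monomorphic-locus count.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param population population label.
#' @param g rarefaction gene count; default from [defaultRarefactionG()]
#'   across all populations present in \code{gm}.
#' @param seed seed for the Monte-Carlo branch of the Hardy-Weinberg tests.
#' @param hweSteps Monte-Carlo steps for large Hardy-Weinberg tables.
#' @return a [PopulationSummary-class].
#' @export
populationSummary <- function(gm, population, g = NULL, seed = 1L,
                              hweSteps = 20000L) {
  aft <- alleleFrequencies(gm)
  checkPop(aft, population)
  if (is.null(g)) g <- defaultRarefactionG(aft)
  n <- sum(gm@populations == population)
  a <- meanAllelesPerLocus(aft, population)
  r <- allelicRichness(gm, population, g)
  ho <- observedHeterozygosity(gm, population)
  he <- suppressWarnings(expectedHeterozygosity(gm, population))
  ra <- rareAlleles(aft, population)
  mono <- countMonomorphicLoci(aft, population)
  fis <- tryCatch(wcFstats(gm, population)$FIS, error = function(e) NA_real_)
  poly <- names(which(aft@alleleCounts[population, ] > 1L))
  hweP <- NA_real_
  if (length(poly)) {
    ps <- vapply(seq_along(poly), function(i)
      hweExactTest(gm, population, poly[i], nSteps = hweSteps,
                   seed = seed + i), numeric(1))
    ps <- ps[!is.na(ps)]
    if (length(ps)) {
      X <- -2 * sum(log(pmax(ps, 1e-300)))
      hweP <- pchisq(X, df = 2 * length(ps), lower.tail = FALSE)
    }
  }
  new("PopulationSummary", population = population, n = as.integer(n),
      a = a$mean, r = r$mean, g = as.numeric(r$g),
      HO = ho$mean, HE = he$mean, FIS = fis, hweP = hweP,
      rareMean = ra$mean, rareSD = ra$sd,
      monomorphicLoci = as.integer(mono))
}

setMethod("show", "PopulationSummary", function(object) {
  cat(sprintf("PopulationSummary '%s' (n = %d)\n", object@population,
              object@n))
  cat(sprintf("  a = %.2f  r = %.2f (g = %g)  HO = %.3f  HE = %.3f\n",
              object@a, object@r, object@g, object@HO, object@HE))
  cat(sprintf("  FIS = %s  HWE p = %s  rA = %.3f (+/- %.3f)  monomorphic: %d\n",
              ifelse(is.na(object@FIS), "NA", sprintf("%.3f", object@FIS)),
              ifelse(is.na(object@hweP), "NA", sprintf("%.3f", object@hweP)),
              object@rareMean,
              ifelse(is.na(object@rareSD), NA, object@rareSD),
              object@monomorphicLoci))
})

#' Coerce summaries to a table row
#'
#' @param x a [PopulationSummary-class].
#' @param ... unused.
#' @return one-row data.frame.
#' @export
summaryRow <- function(x, ...) {
  data.frame(population = x@population, n = x@n, a = x@a, r = x@r,
             HO = x@HO, HE = x@HE, FIS = x@FIS, hweP = x@hweP,
             rA = x@rareMean, rA_sd = x@rareSD,
             monomorphic = x@monomorphicLoci,
             stringsAsFactors = FALSE)
}
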