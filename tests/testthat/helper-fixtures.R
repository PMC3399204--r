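# In-code fixtures shared across the suite.

# a small multi-population genotype set with known per-locus frequencies
toyFreqs <- function() {
  list(L1 = c(`1` = 0.6, `2` = 0.3, `3` = 0.1),
       L2 = c(`1` = 0.5, `2` = 0.5),
       L3 = c(`1` = 1.0),
       L4 = c(`1` = 0.25, `2` = 0.25, `3` = 0.25, `4` = 0.25))
}

# deterministic hand-built GenotypeMatrix from a list of call matrices;
# calls[[pop]] is a list of per-individual integer vectors c(a1,b1,a2,b2,...)
handGenotypes <- function(calls, lociNames) {
  pops <- names(calls)
  rowsA <- list(); rowsB <- list(); labels <- character(0); ids <- character(0)
  for (p in pops) {
    for (i in seq_along(calls[[p]])) {
      v <- calls[[p]][[i]]
      a <- v[seq(1, length(v), 2)]
      b <- v[seq(2, length(v), 2)]
      rowsA[[length(rowsA) + 1]] <- as.integer(a)
      rowsB[[length(rowsB) + 1]] <- as.integer(b)
      labels <- c(labels, p)
      ids <- c(ids, sprintf("%s_%d", p, i))
    }
  }
  islandpop:::newGenotypeMatrix(ids, lociNames, labels,
                                do.call(rbind, rowsA), do.call(rbind, rowsB))
}

# a 13-locus fixture shaped like a severely bottlenecked island population:
# 8 monomorphic loci, 5 weakly polymorphic
depauperateIslandFixture <- function(seed = 42) {
  freqs <- c(
    lapply(1:8, function(i) c(`5` = 1.0)),
    lapply(1:5, function(i) c(`5` = 0.93, `6` = 0.07)))
  names(freqs) <- sprintf("L%02d", 1:13)
  generateGenotypes("relict", 21, freqs, seed = seed)
}

# independent Weir-Cockerham computation via the ANOVA mean-squares route,
# coded separately from the package's summed-components implementation
msFstOracle <- function(gm, pops) {
  callList <- genotypeCalls(gm)
  labs <- populations(gm)
  thetaNum <- 0; thetaDen <- 0
  fNum <- 0; fDen <- 0
  for (l in seq_along(loci(gm))) {
    genesByPop <- lapply(pops, function(p) {
      sel <- labs == p
      a <- callList$a[sel, l]; b <- callList$b[sel, l]
      ok <- !is.na(a)
      list(a = a[ok], b = b[ok])
    })
    alleles <- sort(unique(unlist(lapply(genesByPop,
                                         function(g) c(g$a, g$b)))))
    if (length(alleles) < 2) next
    ns <- vapply(genesByPop, function(g) length(g$a), numeric(1))
    use <- ns > 0
    genesByPop <- genesByPop[use]; ns <- ns[use]
    r <- length(ns)
    nbar <- mean(ns); nsum <- sum(ns)
    nc <- if (r > 1) (nsum - sum(ns^2) / nsum) / (r - 1) else NA
    for (al in alleles) {
      p_i <- vapply(genesByPop, function(g)
        mean(c(g$a, g$b) == al), numeric(1))
      h_i <- vapply(genesByPop, function(g)
        mean((g$a == al) != (g$b == al)), numeric(1))
      pbar <- sum(ns * p_i) / nsum
      hbar <- sum(ns * h_i) / nsum
      # ANOVA mean squares (Weir 1996 notation)
      MSP <- if (r > 1) sum(2 * ns * (p_i - pbar)^2) / (r - 1) else 0
      MSI <- sum(2 * ns * p_i * (1 - p_i) - ns * h_i / 2) / (nsum - r)
      MSG <- hbar / 2
      s2A <- (MSP - MSI) / (2 * nc)
      s2B <- (MSI - MSG) / 2
      s2W <- MSG
      if (r > 1) {
        thetaNum <- thetaNum + s2A
        thetaDen <- thetaDen + s2A + s2B + s2W
      }
      fNum <- fNum + s2B
      fDen <- fDen + s2B + s2W
    }
  }
  list(FST = if (thetaDen != 0) thetaNum / thetaDen else NA,
       FIS = if (fDen != 0) fNum / fDen else NA)
}

# capture histories with optional permanent emigration: closed simulation,
# then each animal leaves after an independent geometric residence time
simulateOpen <- function(Ntrue, T, p, departRate, seed) {
  set.seed(seed)
  y <- matrix(rbinom(Ntrue * T, 1, p), Ntrue, T)
  if (departRate > 0) {
    leave <- 1 + rgeom(Ntrue, departRate)
    for (i in seq_len(Ntrue)) if (leave[i] < T)
      y[i, (leave[i] + 1):T] <- 0L
  }
  keep <- rowSums(y) > 0
  y <- y[keep, , drop = FALSE]
  ids <- sprintf("x%04d", seq_len(nrow(y)))
  dimnames(y) <- list(ids, sprintf("o%02d", seq_len(T)))
  new("CaptureHistory", individuals = ids,
      occasions = colnames(y), detections = y,
      covariates = data.frame(row.names = ids), scaling = list())
}

# conditional likelihood for the constant-probability model: closed form
# L(p) proportional to p^C (1-p)^(DT-C) / (1 - (1-p)^T)^D
m0GridMLE <- function(D, T, C, resolution = 1e-5) {
  p <- seq(resolution, 1 - resolution, by = resolution)
  ll <- C * log(p) + (D * T - C) * log(1 - p) - D * log(1 - (1 - p)^T)
  pHat <- p[which.max(ll)]
  list(pHat = pHat, Nhat = D / (1 - (1 - pHat)^T), logLik = max(ll))
}
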