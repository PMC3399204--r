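#' Tabulate allele counts and frequencies per population and locus
#'
#' Each non-missing diploid call contributes two genes; individuals missing at
#' a locus are dropped from that locus only.  A population x locus cell with
#' no data is left empty (gene count 0) and skipped by downstream statistics.
#'
#' @param gm a [GenotypeMatrix-class].
#' @return an [AlleleFreqTable-class].
#' @examples
#' gm <- generateGenotypes(popLabel = "demo", n = 20,
#'                         freqs = list(L1 = c(`1` = 0.6, `2` = 0.4)),
#'                         seed = 1)
#' aft <- alleleFrequencies(gm)
#' head(freqTable(aft))
#' @export
alleleFrequencies <- function(gm) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (nInd(gm) == 0) stop("empty GenotypeMatrix")
  pops <- unique(gm@populations)
  L <- nLoci(gm)
  gc <- matrix(0L, length(pops), L, dimnames = list(pops, gm@loci))
  ac <- gc
  rows <- vector("list", length(pops) * L)
  r <- 0L
  for (p in pops) {
    pi <- gm@populations == p
    for (l in seq_len(L)) {
      genes <- c(gm@alleleA[pi, l], gm@alleleB[pi, l])
      genes <- genes[!is.na(genes)]
      if (!length(genes)) next
      cnt <- table(genes)
      gc[p, l] <- length(genes)
      ac[p, l] <- length(cnt)
      r <- r + 1L
      rows[[r]] <- data.frame(
        population = p, locus = gm@loci[l],
        allele = as.integer(names(cnt)),
        count = as.integer(cnt),
        freq = as.integer(cnt) / length(genes),
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (r) do.call(rbind, rows[seq_len(r)]) else
    data.frame(population = character(0), locus = character(0),
               allele = integer(0), count = integer(0), freq = numeric(0))
  rownames(tab) <- NULL
  new("AlleleFreqTable", tab = tab, geneCounts = gc, alleleCounts = ac)
}

freqsFor <- function(aft, population, locus) {
  t <- aft@tab
  sel <- t$population == population & t$locus == locus
  setNames(t$freq[sel], t$allele[sel])
}

checkPop <- function(aft, population) {
  if (!population %in% rownames(aft@geneCounts))
    stop("unknown population label: ", population)
}

#' Private (unique) alleles of a focal population
#'
#' Alleles observed in the focal population but in none of the reference
#' populations, reported per locus.
#'
#' @param aft an [AlleleFreqTable-class].
#' @param focal focal population label.
#' @param reference character vector of reference population labels.
#' @return named list (by locus) of integer allele vectors; loci with no
#'   private allele map to an empty vector.
#' @export
privateAlleles <- function(aft, focal, reference) {
  checkPop(aft, focal)
  for (p in reference) checkPop(aft, p)
  t <- aft@tab
  out <- lapply(loci(aft), function(l) {
    mine <- t$allele[t$population == focal & t$locus == l & t$freq > 0]
    theirs <- t$allele[t$population %in% reference & t$locus == l &
                         t$freq > 0]
    sort(setdiff(mine, theirs))
  })
  setNames(out, loci(aft))
}

#' Rare alleles per locus
#'
#' Counts alleles segregating at frequency at or below \code{threshold}
#' (boundary inclusive) within one population, and summarizes the counts as a
#' mean and standard deviation over loci with data -- the "rA" summary of
#' population tables.
#'
#' @param aft an [AlleleFreqTable-class].
#' @param population population label.
#' @param threshold frequency cutoff in (0, 1); default 0.05.
#' @return list with \code{perLocus} (named integer vector), \code{mean} and
#'   \code{sd} over loci with data.
#' @export
rareAlleles <- function(aft, population, threshold = 0.05) {
  checkPop(aft, population)
  if (!(threshold > 0 && threshold < 1))
    stop("threshold must lie in (0, 1)")
  t <- aft@tab
  has <- aft@geneCounts[population, ] > 0
  per <- vapply(loci(aft), function(l) {
    sel <- t$population == population & t$locus == l
    sum(t$freq[sel] > 0 & t$freq[sel] <= threshold)
  }, integer(1))
  vals <- per[has]
  list(perLocus = per,
       mean = if (length(vals)) mean(vals) else NA_real_,
       sd = if (length(vals) > 1) sd(vals) else NA_real_)
}

#' Mean number of alleles per locus
#'
#' @param aft an [AlleleFreqTable-class].
#' @param population population label.
#' @return list with \code{perLocus} counts and their \code{mean} over loci
#'   with data.
#' @export
meanAllelesPerLocus <- function(aft, population) {
  checkPop(aft, population)
  per <- aft@alleleCounts[population, ]
  has <- aft@geneCounts[population, ] > 0
  list(perLocus = per, mean = mean(per[has]))
}

#' Count loci monomorphic within a population
#'
#' A locus is monomorphic when exactly one allele is observed; loci with no
#' data are not counted.
#'
#' @param aft an [AlleleFreqTable-class].
#' @param population population label.
#' @return integer count.
#' @export
countMonomorphicLoci <- function(aft, population) {
  checkPop(aft, population)
  sum(aft@alleleCounts[population, ] == 1L)
}
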