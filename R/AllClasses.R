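#' @import methods
#' @importFrom stats optim optimHess pchisq pnorm qnorm rbinom rmultinom
#'   rnorm rgamma runif sd setNames uniroot quantile plogis qlogis
#' @importFrom graphics plot lines points par
#' @importFrom utils read.table write.table combn
NULL

MISSING_ALLELE <- NA_integer_

#' Multilocus codominant genotypes with population labels
#'
#' An individuals-by-loci table of diploid microsatellite calls.  Each call is
#' an unordered pair of positive integer allele labels, stored as two parallel
#' matrices with the smaller label first; a missing call is \code{NA} in both.
#' Population membership is carried per individual, in file order.
#'
#' @slot individuals character vector of individual identifiers.
#' @slot loci character vector of locus names.
#' @slot populations character vector, one label per individual, drawn from
#'   \code{levels}' order of first appearance.
#' @slot alleleA,alleleB integer matrices (individuals x loci); for every
#'   non-missing call \code{alleleA <= alleleB}, both positive.
#'
#' @seealso [readGenepop()], [alleleFrequencies()], [populationSummary()]
#' @export
setClass("GenotypeMatrix",
  representation(
    individuals = "character",
    loci        = "character",
    populations = "character",
    alleleA     = "matrix",
    alleleB     = "matrix"
  )
)

setValidity("GenotypeMatrix", function(object) {
  n <- length(object@individuals)
  L <- length(object@loci)
  msgs <- character(0)
  if (!identical(dim(object@alleleA), c(n, L)) ||
      !identical(dim(object@alleleB), c(n, L)))
    msgs <- c(msgs, "allele matrices must be individuals x loci")
  if (length(object@populations) != n)
    msgs <- c(msgs, "one population label per individual required")
  if (anyDuplicated(object@loci))
    msgs <- c(msgs, "locus names must be unique")
  a <- object@alleleA; b <- object@alleleB
  if (any(is.na(a) != is.na(b)))
    msgs <- c(msgs, "half-missing calls are not allowed")
  ok <- !is.na(a)
  if (any(a[ok] < 1L) || any(b[ok] < 1L))
    msgs <- c(msgs, "allele labels must be positive integers")
  if (any(a[ok] > b[ok]))
    msgs <- c(msgs, "calls must be stored with the smaller allele first")
  if (length(msgs)) msgs else TRUE
})

#' Per-population, per-locus allele frequencies
#'
#' Long-format allele counts and relative frequencies together with gene
#' counts (2 x non-missing genotypes).  Individuals missing at a locus are
#' excluded from that locus only, so gene counts vary across loci.
#'
#' @slot tab data.frame with columns \code{population}, \code{locus},
#'   \code{allele}, \code{count}, \code{freq}.
#' @slot geneCounts integer matrix populations x loci (2 x genotyped).
#' @slot alleleCounts integer matrix populations x loci, distinct alleles
#'   observed (0 where no data).
#' @export
setClass("AlleleFreqTable",
  representation(
    tab          = "data.frame",
    geneCounts   = "matrix",
    alleleCounts = "matrix"
  )
)

setValidity("AlleleFreqTable", function(object) {
  msgs <- character(0)
  need <- c("population", "locus", "allele", "count", "freq")
  if (!all(need %in% names(object@tab)))
    msgs <- c(msgs, "tab must have population/locus/allele/count/freq columns")
  if (any(object@geneCounts %% 2L != 0L))
    msgs <- c(msgs, "gene counts must be even")
  if (nrow(object@tab)) {
    s <- tapply(object@tab$freq,
                paste(object@tab$population, object@tab$locus, sep = "\r"),
                sum)
    if (any(abs(s - 1) > 1e-12))
      msgs <- c(msgs, "frequencies must sum to 1 per population x locus")
    if (any(object@tab$freq < 0))
      msgs <- c(msgs, "frequencies must be nonnegative")
  }
  if (length(msgs)) msgs else TRUE
})

#' Per-population diversity summary
#'
#' One population's row of a standard microsatellite summary table: sample
#' size, mean alleles per locus, rarefied allelic richness, observed and
#' unbiased expected heterozygosity, the multilocus within-population
#' inbreeding coefficient, a combined Hardy-Weinberg p-value, and the rare
#' allele summary.
#'
#' @slot population label.
#' @slot n individuals genotyped.
#' @slot a mean observed alleles per locus.
#' @slot r rarefied allelic richness averaged over loci.
#' @slot g rarefaction gene count used for \code{r}.
#' @slot HO,HE mean observed / unbiased expected heterozygosity.
#' @slot FIS multilocus Weir-Cockerham f (NA when undefined).
#' @slot hweP Fisher-combined Hardy-Weinberg exact p over polymorphic loci.
#' @slot rareMean,rareSD rare-allele (freq <= 0.05) count mean and SD per
#'   locus.
#' @slot monomorphicLoci count of loci with a single observed allele.
#' @export
setClass("PopulationSummary",
  representation(
    population = "character", n = "integer",
    a = "numeric", r = "numeric", g = "numeric",
    HO = "numeric", HE = "numeric",
    FIS = "numeric", hweP = "numeric",
    rareMean = "numeric", rareSD = "numeric",
    monomorphicLoci = "integer"
  )
)

#' Pairwise or global F_ST estimate
#'
#' @slot pair the two population labels, or \code{"global"}.
#' @slot theta multilocus Weir-Cockerham estimate.
#' @slot ciLow,ciHigh 95\% bootstrap-over-loci percentile bounds.
#' @slot permP permutation p-value (add-one estimator), NA if not computed.
#' @slot nPerm,nBoot replicate counts used.
#' @export
setClass("FstResult",
  representation(
    pair = "character", theta = "numeric",
    ciLow = "numeric", ciHigh = "numeric",
    permP = "numeric", nPerm = "integer", nBoot = "integer"
  )
)

#' Binary capture histories over discrete occasions
#'
#' Detection records of uniquely marked animals over ordered trapping
#' occasions (e.g. pooled survey months), with per-individual covariates held
#' constant at their first recorded value.  Only animals captured at least
#' once appear, matching how live-trapping data arise.
#'
#' @slot individuals character identifiers.
#' @slot occasions character occasion labels, in temporal order.
#' @slot detections integer 0/1 matrix individuals x occasions; every row has
#'   at least one 1.
#' @slot covariates data.frame of per-individual numeric covariates (may have
#'   zero columns), rows aligned with \code{individuals}.
#' @slot scaling named list recording the centre/spread used by
#'   [normalizeCovariates()] (empty until normalization).
#' @export
setClass("CaptureHistory",
  representation(
    individuals = "character",
    occasions   = "character",
    detections  = "matrix",
    covariates  = "data.frame",
    scaling     = "list"
  )
)

setValidity("CaptureHistory", function(object) {
  msgs <- character(0)
  n <- length(object@individuals)
  if (!identical(dim(object@detections),
                 c(n, length(object@occasions))))
    msgs <- c(msgs, "detections must be individuals x occasions")
  if (n > 0 && !all(object@detections %in% c(0L, 1L)))
    msgs <- c(msgs, "detections must be 0/1")
  if (n > 0 && any(rowSums(object@detections) < 1))
    msgs <- c(msgs, "every individual must have at least one detection")
  if (nrow(object@covariates) != n)
    msgs <- c(msgs, "covariates must have one row per individual")
  if (length(msgs)) msgs else TRUE
})

#' Specification of a closed-population capture-probability model
#'
#' The classical closed-population model family indexed by three switches:
#' time variation (t), behavioural trap response (b), and individual
#' heterogeneity via a numeric covariate (h, optionally quadratic).  The
#' 2 x 2 x 2 grid yields the eight models M(0) ... M(tbh).
#'
#' @slot time logical; occasion effects on the logit scale.
#' @slot behavior logical; permanent trap-response indicator on recaptures.
#' @slot heterogeneity one of \code{"none"}, \code{"linear"},
#'   \code{"quadratic"}.
#' @slot covariate name of the covariate column used when heterogeneity is on.
#' @export
setClass("CMRModelSpec",
  representation(
    time          = "logical",
    behavior      = "logical",
    heterogeneity = "character",
    covariate     = "character"
  ),
  prototype(time = FALSE, behavior = FALSE,
            heterogeneity = "none", covariate = NA_character_)
)

setValidity("CMRModelSpec", function(object) {
  msgs <- character(0)
  if (!object@heterogeneity %in% c("none", "linear", "quadratic"))
    msgs <- c(msgs, "heterogeneity must be none/linear/quadratic")
  if (object@heterogeneity != "none" && is.na(object@covariate))
    msgs <- c(msgs, "heterogeneity models need a covariate name")
  if (length(msgs)) msgs else TRUE
})

#' A fitted Huggins conditional-likelihood model
#'
#' @slot spec the [CMRModelSpec-class] fitted.
#' @slot coef named numeric coefficients on the logit scale.
#' @slot vcov coefficient covariance (inverse observed information).
#' @slot logLik maximized conditional log-likelihood.
#' @slot AIC \eqn{-2\ell + 2k}.
#' @slot Nhat Horvitz-Thompson abundance estimate.
#' @slot seNhat its standard error (binomial + delta-method components).
#' @slot D number of distinct animals observed.
#' @slot converged logical.
#' @export
setClass("CMRFit",
  representation(
    spec      = "CMRModelSpec",
    coef      = "numeric",
    vcov      = "matrix",
    logLik    = "numeric",
    AIC       = "numeric",
    Nhat      = "numeric",
    seNhat    = "numeric",
    D         = "integer",
    converged = "logical"
  )
)

#' Result of a population-closure test
#'
#' @slot test test name.
#' @slot statistic test statistic (z or chi-square).
#' @slot df degrees of freedom (NA for the z test).
#' @slot p p-value; low values indicate lack of closure.
#' @slot verdict human-readable summary.
#' @export
setClass("ClosureResult",
  representation(
    test      = "character",
    statistic = "numeric",
    df        = "numeric",
    p         = "numeric",
    verdict   = "character"
  )
)

setValidity("ClosureResult", function(object) {
  if (!is.na(object@p) && (object@p < 0 || object@p > 1))
    "p must lie in [0, 1]" else TRUE
})

#' Monte-Carlo drift trajectories
#'
#' Per-generation summaries of Wright-Fisher replicate simulations: mean gene
#' diversity and mean surviving allele count over loci and replicates, with
#' empirical 2.5/97.5 percentile envelopes across replicates.
#'
#' @slot generations integer vector 0..t_max.
#' @slot meanHet,hetLow,hetHigh numeric vectors along \code{generations}.
#' @slot meanAlleles,allelesLow,allelesHigh numeric vectors.
#' @slot replicateHet optional replicates x generations matrix of per-replicate
#'   mean heterozygosity (empty matrix unless retained).
#' @slot Ne,replicates,seed the configuration used.
#' @export
setClass("DriftTrajectory",
  representation(
    generations  = "integer",
    meanHet      = "numeric",
    hetLow       = "numeric",
    hetHigh      = "numeric",
    meanAlleles  = "numeric",
    allelesLow   = "numeric",
    allelesHigh  = "numeric",
    replicateHet = "matrix",
    Ne           = "numeric",
    replicates   = "integer",
    seed         = "integer"
  )
)

setValidity("DriftTrajectory", function(object) {
  msgs <- character(0)
  G <- length(object@generations)
  if (length(object@meanHet) != G || length(object@meanAlleles) != G)
    msgs <- c(msgs, "summary vectors must align with generations")
  if (any(object@meanHet < -1e-12 | object@meanHet > 1 + 1e-12))
    msgs <- c(msgs, "heterozygosity must lie in [0, 1]")
  if (any(object@hetLow > object@hetHigh + 1e-12))
    msgs <- c(msgs, "envelope bounds out of order")
  if (length(msgs)) msgs else TRUE
})
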