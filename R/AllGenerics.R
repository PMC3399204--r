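#' Accessors for islandpop classes
#'
#' Small generics extracting the components of the package's S4 objects;
#' user code should use these rather than reach into slots.
#'
#' @param x an islandpop object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))
#' @rdname accessors
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))
#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))
#' @rdname accessors
#' @export
setGeneric("popNames", function(x) standardGeneric("popNames"))
#' @rdname accessors
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))
#' @rdname accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))
#' @rdname accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))
#' @rdname accessors
#' @export
setGeneric("freqTable", function(x) standardGeneric("freqTable"))
#' @rdname accessors
#' @export
setGeneric("geneCounts", function(x) standardGeneric("geneCounts"))
#' @rdname accessors
#' @export
setGeneric("alleleCounts", function(x) standardGeneric("alleleCounts"))
#' @rdname accessors
#' @export
setGeneric("occasions", function(x) standardGeneric("occasions"))
#' @rdname accessors
#' @export
setGeneric("detections", function(x) standardGeneric("detections"))
#' @rdname accessors
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))
#' @rdname accessors
#' @export
setGeneric("abundance", function(x) standardGeneric("abundance"))
#' @rdname accessors
#' @export
setGeneric("modelSpec", function(x) standardGeneric("modelSpec"))

setMethod("individuals", "GenotypeMatrix", function(x) x@individuals)
setMethod("loci", "GenotypeMatrix", function(x) x@loci)
setMethod("populations", "GenotypeMatrix", function(x) x@populations)
setMethod("popNames", "GenotypeMatrix", function(x) unique(x@populations))
setMethod("nInd", "GenotypeMatrix", function(x) length(x@individuals))
setMethod("nLoci", "GenotypeMatrix", function(x) length(x@loci))

setMethod("genotypeCalls", "GenotypeMatrix", function(x) {
  list(a = x@alleleA, b = x@alleleB)
})

setMethod("freqTable", "AlleleFreqTable", function(x) x@tab)
setMethod("geneCounts", "AlleleFreqTable", function(x) x@geneCounts)
setMethod("alleleCounts", "AlleleFreqTable", function(x) x@alleleCounts)
setMethod("popNames", "AlleleFreqTable", function(x) rownames(x@geneCounts))
setMethod("loci", "AlleleFreqTable", function(x) colnames(x@geneCounts))

setMethod("individuals", "CaptureHistory", function(x) x@individuals)
setMethod("nInd", "CaptureHistory", function(x) length(x@individuals))
setMethod("occasions", "CaptureHistory", function(x) x@occasions)
setMethod("detections", "CaptureHistory", function(x) x@detections)
setMethod("covariates", "CaptureHistory", function(x) x@covariates)

setMethod("abundance", "CMRFit", function(x) x@Nhat)
setMethod("modelSpec", "CMRFit", function(x) x@spec)

#' @importFrom stats coef
#' @export
setMethod("coef", "CMRFit", function(object, ...) object@coef)
#' @importFrom stats vcov
#' @export
setMethod("vcov", "CMRFit", function(object, ...) object@vcov)
#' @importFrom stats logLik
#' @export
setMethod("logLik", "CMRFit", function(object, ...) object@logLik)
#' @importFrom stats AIC
#' @export
setMethod("AIC", "CMRFit", function(object, ..., k = 2) object@AIC)

#' Canonical label of a capture-probability model
#'
#' \code{"M(0)"}, \code{"M(t)"}, \code{"M(b)"}, \code{"M(h)"} and their
#' combinations; the quadratic heterogeneity variant is \code{"M(h2)"}.
#'
#' @param spec a [CMRModelSpec-class].
#' @return character label.
#' @export
modelLabel <- function(spec) {
  tag <- paste0(if (spec@time) "t" else "",
                if (spec@behavior) "b" else "",
                if (spec@heterogeneity != "none") "h" else "")
  if (tag == "") tag <- "0"
  if (spec@heterogeneity == "quadratic") tag <- paste0(tag, "2")
  paste0("M(", tag, ")")
}

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nInd(object), "individuals x",
      nLoci(object), "loci\n")
  tbl <- table(factor(object@populations, levels = unique(object@populations)))
  cat("populations:",
      paste(sprintf("%s (n=%d)", names(tbl), as.integer(tbl)),
            collapse = ", "), "\n")
  miss <- mean(is.na(object@alleleA))
  cat(sprintf("missing calls: %.1f%%\n", 100 * miss))
})

setMethod("show", "AlleleFreqTable", function(object) {
  cat("AlleleFreqTable:", nrow(object@geneCounts), "populations x",
      ncol(object@geneCounts), "loci,",
      nrow(object@tab), "allele records\n")
})

setMethod("show", "CaptureHistory", function(object) {
  cat("CaptureHistory:", nInd(object), "individuals x",
      length(object@occasions), "occasions;",
      sum(object@detections), "detections\n")
  if (ncol(object@covariates))
    cat("covariates:", paste(names(object@covariates), collapse = ", "), "\n")
})

setMethod("show", "CMRFit", function(object) {
  cat(sprintf("%s fit: N-hat = %.2f (SE %.2f), AIC = %.2f, logLik = %.2f%s\n",
              modelLabel(object@spec), object@Nhat, object@seNhat,
              object@AIC, object@logLik,
              if (object@converged) "" else " [NOT CONVERGED]"))
})

setMethod("show", "ClosureResult", function(object) {
  cat(sprintf("%s: statistic = %.3f%s, p = %.4g\n  %s\n",
              object@test, object@statistic,
              if (is.na(object@df)) "" else sprintf(" (df = %g)", object@df),
              object@p, object@verdict))
})

setMethod("show", "DriftTrajectory", function(object) {
  G <- length(object@generations) - 1L
  cat(sprintf(paste0("DriftTrajectory: Ne = %g, %d replicates, ",
                     "%d generations\n"),
              object@Ne, object@replicates, G))
  cat(sprintf("  H: %.3f -> %.3f;  mean alleles: %.2f -> %.2f\n",
              object@meanHet[1], object@meanHet[length(object@meanHet)],
              object@meanAlleles[1],
              object@meanAlleles[length(object@meanAlleles)]))
})
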