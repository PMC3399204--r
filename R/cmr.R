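# Closed-population capture-recapture by Huggins conditional likelihood.
# Capture probabilities are modeled on the logit scale; the likelihood
# conditions on each animal's probability of being caught at least once,
# which excludes the behavioural (trap-response) term because an uncaptured
# animal cannot yet have responded.

#' Build a CaptureHistory from capture-event records
#'
#' Reads a delimited file (or takes a data.frame) with one row per capture
#' event: individual id, occasion label, and optional numeric covariate
#' columns.  Repeated captures of an animal within one occasion collapse to a
#' single detection.  Covariates are taken from each individual's first row
#' in the file and held constant.  Occasion order follows
#' \code{occasionLevels} when given, otherwise first appearance in the file.
#'
#' @param path path to a delimited text file, or a data.frame.
#' @param idCol,occasionCol column names (defaults \code{"id"},
#'   \code{"occasion"}).
#' @param covariateCols character vector of covariate column names (default:
#'   every remaining numeric column).
#' @param occasionLevels optional full ordered set of occasion labels.
#' @param sep field separator for files (default \code{","}).
#' @return a [CaptureHistory-class].
#' @export
readCaptureEvents <- function(path, idCol = "id", occasionCol = "occasion",
                              covariateCols = NULL, occasionLevels = NULL,
                              sep = ",") {
  ev <- if (is.data.frame(path)) path else
    read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  for (col in c(idCol, occasionCol))
    if (!col %in% names(ev)) stop("missing column: ", col)
  if (!nrow(ev)) stop("no capture events")
  ev[[idCol]] <- as.character(ev[[idCol]])
  ev[[occasionCol]] <- as.character(ev[[occasionCol]])
  if (is.null(occasionLevels)) {
    occasionLevels <- unique(ev[[occasionCol]])
  } else {
    bad <- setdiff(ev[[occasionCol]], occasionLevels)
    if (length(bad))
      stop("capture event with unknown occasion label: ", bad[1])
  }
  if (is.null(covariateCols)) {
    rest <- setdiff(names(ev), c(idCol, occasionCol))
    covariateCols <- rest[vapply(ev[rest], is.numeric, logical(1))]
  }
  ids <- unique(ev[[idCol]])
  det <- matrix(0L, length(ids), length(occasionLevels),
                dimnames = list(ids, occasionLevels))
  det[cbind(match(ev[[idCol]], ids),
            match(ev[[occasionCol]], occasionLevels))] <- 1L
  firstRow <- ev[!duplicated(ev[[idCol]]), , drop = FALSE]
  covs <- firstRow[match(ids, firstRow[[idCol]]), covariateCols,
                   drop = FALSE]
  rownames(covs) <- ids
  new("CaptureHistory", individuals = ids, occasions = occasionLevels,
      detections = det, covariates = covs, scaling = list())
}

#' Write capture events back to a delimited file
#'
#' Emits one row per (individual, occasion) detection with the covariate
#' columns, in a form [readCaptureEvents()] parses back to an equivalent
#' history.
#'
#' @param ch a [CaptureHistory-class].
#' @param path output path.
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
writeCaptureEvents <- function(ch, path, sep = ",") {
  idx <- which(ch@detections == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- data.frame(id = ch@individuals[idx[, 1]],
                    occasion = ch@occasions[idx[, 2]],
                    stringsAsFactors = FALSE)
  for (nm in colnames(ch@covariates))
    out[[nm]] <- ch@covariates[[nm]][idx[, 1]]
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pool capture occasions
#'
#' Merges groups of occasions (e.g. adjacent sparse months): a pooled
#' detection is the logical OR over the group's members.
#'
#' @param ch a [CaptureHistory-class].
#' @param grouping named list; each element is a character vector of occasion
#'   labels to merge, named by the pooled label.  Occasions not mentioned are
#'   kept as-is, in their original relative order (a pooled occasion takes
#'   the position of its earliest member).
#' @return a [CaptureHistory-class].
#' @export
poolOccasions <- function(ch, grouping) {
  members <- unlist(grouping, use.names = FALSE)
  if (anyDuplicated(members))
    stop("grouping assigns some occasion to more than one group")
  bad <- setdiff(members, ch@occasions)
  if (length(bad)) stop("unknown occasion label in grouping: ", bad[1])
  groupOf <- setNames(rep(names(grouping), lengths(grouping)), members)
  lab <- ifelse(ch@occasions %in% members, groupOf[ch@occasions],
                ch@occasions)
  newLabels <- unique(lab)
  det <- sapply(newLabels, function(g)
    as.integer(rowSums(ch@detections[, lab == g, drop = FALSE]) > 0))
  det <- matrix(det, nrow = nInd(ch),
                dimnames = list(ch@individuals, newLabels))
  new("CaptureHistory", individuals = ch@individuals, occasions = newLabels,
      detections = det, covariates = ch@covariates, scaling = ch@scaling)
}

#' Normalize per-individual covariates
#'
#' Z-score transform using the mean and the population-style standard
#' deviation (denominator \eqn{n}) over captured individuals; the transform
#' parameters are stored in the object's \code{scaling} metadata so fits are
#' reproducible.
#'
#' @param ch a [CaptureHistory-class].
#' @param names covariate columns to normalize (default all).
#' @return a [CaptureHistory-class].
#' @export
normalizeCovariates <- function(ch, names = NULL) {
  if (is.null(names)) names <- colnames(ch@covariates)
  covs <- ch@covariates
  scaling <- ch@scaling
  for (nm in names) {
    if (!nm %in% colnames(covs)) stop("unknown covariate: ", nm)
    x <- covs[[nm]]
    if (!is.numeric(x)) stop("covariate not numeric: ", nm)
    mu <- mean(x)
    sdn <- sqrt(mean((x - mu)^2))
    if (sdn == 0) stop("covariate has zero variance: ", nm)
    covs[[nm]] <- (x - mu) / sdn
    scaling[[nm]] <- c(center = mu, scale = sdn)
  }
  new("CaptureHistory", individuals = ch@individuals,
      occasions = ch@occasions, detections = ch@detections,
      covariates = covs, scaling = scaling)
}

#' Construct a capture-probability model specification
#'
#' @param time logical, occasion effects.
#' @param behavior logical, permanent trap-response effect on recaptures.
#' @param heterogeneity \code{"none"}, \code{"linear"} or \code{"quadratic"}
#'   covariate dependence.
#' @param covariate covariate name (required unless heterogeneity is
#'   \code{"none"}).
#' @return a [CMRModelSpec-class].
#' @export
cmrModelSpec <- function(time = FALSE, behavior = FALSE,
                         heterogeneity = c("none", "linear", "quadratic"),
                         covariate = NA_character_) {
  new("CMRModelSpec", time = time, behavior = behavior,
      heterogeneity = match.arg(heterogeneity), covariate = covariate)
}

nParams <- function(spec, T) {
  1L + (if (spec@time) T - 1L else 0L) + (if (spec@behavior) 1L else 0L) +
    switch(spec@heterogeneity, none = 0L, linear = 1L, quadratic = 2L)
}

paramNames <- function(spec, T) {
  nm <- "(Intercept)"
  if (spec@time) nm <- c(nm, paste0("occ", 2:T))
  if (spec@behavior) nm <- c(nm, "behavior")
  if (spec@heterogeneity != "none") nm <- c(nm, spec@covariate)
  if (spec@heterogeneity == "quadratic")
    nm <- c(nm, paste0("I(", spec@covariate, "^2)"))
  nm
}

# split a parameter vector into components; returns list(b0, timeEff[T],
# bBehav, covEff[n])
splitParams <- function(par, spec, T, w) {
  pos <- 1L
  b0 <- par[pos]; pos <- pos + 1L
  timeEff <- numeric(T)
  if (spec@time) { timeEff[2:T] <- par[pos:(pos + T - 2L)]; pos <- pos + T - 1L }
  bBehav <- 0
  if (spec@behavior) { bBehav <- par[pos]; pos <- pos + 1L }
  covEff <- numeric(length(w))
  if (spec@heterogeneity != "none") {
    covEff <- par[pos] * w; pos <- pos + 1L
    if (spec@heterogeneity == "quadratic") {
      covEff <- covEff + par[pos] * w^2; pos <- pos + 1L
    }
  }
  list(b0 = b0, timeEff = timeEff, bBehav = bBehav, covEff = covEff)
}

#' Capture probability under a model specification
#'
#' Inverse-logit of the linear predictor: intercept, occasion effect (time
#' models, occasion 1 as reference), behavioural effect for
#' previously-captured animals, and linear or quadratic covariate terms.
#'
#' @param spec a [CMRModelSpec-class].
#' @param params coefficient vector in the order intercept, occasion
#'   contrasts 2..T, behavior, covariate, covariate^2 (model terms only).
#' @param covariate covariate value(s) for the animal (ignored unless the
#'   spec has heterogeneity).
#' @param occasion occasion index (1-based).
#' @param previouslyCaptured logical.
#' @param T number of occasions (needed for time models; default taken as
#'   \code{occasion} otherwise).
#' @return capture probability in (0, 1).
#' @export
captureProbability <- function(spec, params, covariate = 0, occasion = 1L,
                               previouslyCaptured = FALSE, T = max(occasion)) {
  if (length(params) != nParams(spec, T))
    stop(sprintf("expected %d parameters for %s with T = %d, got %d",
                 nParams(spec, T), modelLabel(spec), T, length(params)))
  sp <- splitParams(params, spec, T, covariate)
  eta <- sp$b0 + sp$timeEff[occasion] + sp$bBehav * previouslyCaptured +
    sp$covEff
  plogis(eta)
}

hugginsNegLogLik <- function(par, spec, y, prior, w, T) {
  sp <- splitParams(par, spec, T, w)
  eta0 <- outer(sp$covEff + sp$b0, sp$timeEff, `+`)
  eta <- eta0 + sp$bBehav * prior
  p <- plogis(eta)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  p0 <- plogis(eta0)
  p0 <- pmin(pmax(p0, 1e-12), 1 - 1e-12)
  logPi <- log1p(-exp(rowSums(log1p(-p0))))
  -(sum(y * log(p) + (1 - y) * log(1 - p)) - sum(logPi))
}

hugginsPi <- function(par, spec, w, T) {
  sp <- splitParams(par, spec, T, w)
  eta0 <- outer(sp$covEff + sp$b0, sp$timeEff, `+`)
  p0 <- pmin(pmax(plogis(eta0), 1e-12), 1 - 1e-12)
  -expm1(rowSums(log1p(-p0)))
}

numGradient <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

#' Fit a Huggins conditional-likelihood model
#'
#' Maximizes the capture-history likelihood conditioned on each animal being
#' caught at least once,
#' \deqn{L = \prod_i \prod_j p_{ij}^{y_{ij}} (1-p_{ij})^{1-y_{ij}} / \pi_i,}
#' where \eqn{\pi_i = 1 - \prod_j (1 - \tilde p_{ij})} uses first-capture
#' probabilities (no behavioural term).  Abundance is the Horvitz-Thompson
#' sum \eqn{\hat N = \sum_i 1/\hat\pi_i}; its variance combines the binomial
#' term \eqn{\sum_i (1-\hat\pi_i)/\hat\pi_i^2} with a delta-method term over
#' the coefficient covariance.  Optimization is quasi-Newton (BFGS) from the
#' naive-capture-fraction start plus two jittered restarts.
#'
#' @param ch a [CaptureHistory-class].
#' @param spec a [CMRModelSpec-class].
#' @param seed seed for the jittered restarts.
#' @param maxit optimizer iteration cap.
#' @return a [CMRFit-class].
#' @export
fitHuggins <- function(ch, spec, seed = 1L, maxit = 500L) {
  y <- ch@detections
  T <- ncol(y)
  D <- nrow(y)
  if (T < 2) stop("at least 2 occasions required")
  prior <- t(apply(y, 1, function(r) c(0L, cumsum(r)[-T] > 0)))
  prior <- matrix(as.numeric(prior), D, T)
  w <- if (spec@heterogeneity != "none") {
    if (!spec@covariate %in% colnames(ch@covariates))
      stop("covariate not found in capture history: ", spec@covariate)
    ch@covariates[[spec@covariate]]
  } else numeric(D)
  K <- nParams(spec, T)
  nll <- function(par) hugginsNegLogLik(par, spec, y, prior, w, T)
  start0 <- c(qlogis(min(max(mean(y), 0.01), 0.99)), numeric(K - 1L))
  set.seed(seed)
  starts <- list(start0,
                 start0 + rnorm(K, 0, 0.25),
                 start0 + rnorm(K, 0, 0.5))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, nll, method = "BFGS",
            control = list(maxit = maxit, reltol = 1e-12), hessian = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-10) best <- fit
  }
  if (is.null(best))
    return(new("CMRFit", spec = spec,
               coef = setNames(rep(NA_real_, K), paramNames(spec, T)),
               vcov = matrix(NA_real_, K, K), logLik = NA_real_,
               AIC = NA_real_, Nhat = NA_real_, seNhat = NA_real_,
               D = D, converged = FALSE))
  par <- best$par
  hess <- tryCatch(optimHess(par, nll), error = function(e) NULL)
  V <- if (!is.null(hess))
    tryCatch(solve(hess), error = function(e) matrix(NA_real_, K, K))
  else matrix(NA_real_, K, K)
  converged <- best$convergence == 0 && all(is.finite(par))
  pi <- hugginsPi(par, spec, w, T)
  Nhat <- sum(1 / pi)
  varBin <- sum((1 - pi) / pi^2)
  d <- numGradient(function(b) sum(1 / hugginsPi(b, spec, w, T)), par)
  varDelta <- if (all(is.finite(V))) drop(t(d) %*% V %*% d) else NA_real_
  seN <- sqrt(varBin + max(0, varDelta))
  ll <- -best$value
  names(par) <- paramNames(spec, T)
  dimnames(V) <- list(names(par), names(par))
  new("CMRFit", spec = spec, coef = par, vcov = V, logLik = ll,
      AIC = -2 * ll + 2 * K, Nhat = Nhat, seNhat = seN,
      D = D, converged = converged)
}

#' Fit the closed-population model family
#'
#' Fits the eight models M(0), M(t), M(b), M(h), M(tb), M(th), M(bh), M(tbh)
#' (heterogeneity as a linear covariate effect), plus the quadratic M(h)
#' variant when requested.  Individual model failures are reported without
#' aborting the sweep.
#'
#' @param ch a [CaptureHistory-class].
#' @param covariate covariate name for the heterogeneity models (may be NA to
#'   skip them).
#' @param includeQuadratic also fit quadratic M(h).
#' @param seed passed to each fit.
#' @return named list of [CMRFit-class] objects, sorted by AIC (failed fits
#'   last).
#' @export
fitAllModels <- function(ch, covariate = NA_character_,
                         includeQuadratic = FALSE, seed = 1L) {
  grid <- expand.grid(time = c(FALSE, TRUE), behavior = c(FALSE, TRUE),
                      het = c(FALSE, TRUE))
  if (is.na(covariate)) {
    if (includeQuadratic)
      stop("the quadratic heterogeneity model requires a covariate name")
    grid <- grid[!grid$het, , drop = FALSE]
  }
  specs <- lapply(seq_len(nrow(grid)), function(i)
    cmrModelSpec(time = grid$time[i], behavior = grid$behavior[i],
                 heterogeneity = if (grid$het[i]) "linear" else "none",
                 covariate = covariate))
  if (includeQuadratic)
    specs <- c(specs, list(cmrModelSpec(heterogeneity = "quadratic",
                                        covariate = covariate)))
  fits <- lapply(specs, function(sp)
    tryCatch(fitHuggins(ch, sp, seed = seed), error = function(e) {
      warning(modelLabel(sp), " failed: ", conditionMessage(e))
      new("CMRFit", spec = sp, coef = NA_real_,
          vcov = matrix(NA_real_, 1, 1), logLik = NA_real_, AIC = NA_real_,
          Nhat = NA_real_, seNhat = NA_real_, D = nInd(ch),
          converged = FALSE)
    }))
  names(fits) <- vapply(fits, function(f) modelLabel(f@spec), character(1))
  aics <- vapply(fits, function(f) ifelse(is.na(f@AIC), Inf, f@AIC),
                 numeric(1))
  fits[order(aics)]
}

#' Select the best model by AIC
#'
#' Minimum AIC among converged fits; exact ties go to the model with fewest
#' parameters, then to the earlier model in the canonical order M(0), M(t),
#' M(b), M(h), M(tb), M(th), M(bh), M(tbh), M(h2).
#'
#' @param fits list of [CMRFit-class] objects.
#' @return the selected [CMRFit-class].
#' @export
selectModel <- function(fits) {
  ok <- Filter(function(f) f@converged && is.finite(f@AIC), fits)
  if (!length(ok)) stop("no converged fit to select from")
  canonical <- c("M(0)", "M(t)", "M(b)", "M(h)", "M(tb)", "M(th)", "M(bh)",
                 "M(tbh)", "M(h2)")
  labs <- vapply(ok, function(f) modelLabel(f@spec), character(1))
  aic <- vapply(ok, function(f) f@AIC, numeric(1))
  npar <- vapply(ok, function(f) length(f@coef), numeric(1))
  ord <- order(round(aic, 10), npar, match(labs, canonical))
  ok[[ord[1]]]
}

#' Tabulate a model sweep
#'
#' @param fits list of [CMRFit-class] objects from [fitAllModels()].
#' @return data.frame with model, nPar, logLik, AIC, Nhat, seNhat, converged.
#' @export
modelTable <- function(fits) {
  do.call(rbind, lapply(fits, function(f) data.frame(
    model = modelLabel(f@spec), nPar = length(f@coef),
    logLik = f@logLik, AIC = f@AIC, Nhat = f@Nhat, seNhat = f@seNhat,
    converged = f@converged, stringsAsFactors = FALSE, row.names = NULL)))
}
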