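## Empirical-Bayes two-component mixture of search scores.
##
## Scores s in (0, 1] of a full (unthresholded) batch of best target hits
## are modeled as pi0 * f0(s) + (1 - pi0) * f1(s), where the false
## component f0 is a Gamma density on the score itself (false hits pile up
## at low scores) and the true component f1 is a "mirrored" Gamma, Gumbel
## or Weibull density, i.e. the named density evaluated at (sMax - s), so
## its mode sits near high scores. Expectation maximization alternates
## responsibilities with weighted maximum-likelihood updates of the
## component parameters (numerical, started from the current parameters,
## kept only if they improve the weighted likelihood, so the observed-data
## log-likelihood is non-decreasing up to numerical tolerance).

.EPS <- 1e-9

.dfalse <- function(s, shape, scale) {
  dgamma(pmax(s, .EPS), shape = shape, scale = scale)
}

.dmirror <- function(s, family, par, sMax = 1) {
  x <- pmax(sMax - s, 1e-6)
  switch(family,
    gamma = dgamma(x, shape = par[["shape"]], scale = par[["scale"]]),
    weibull = dweibull(x, shape = par[["shape"]], scale = par[["scale"]]),
    gumbel = {
      z <- (x - par[["loc"]]) / par[["scale"]]
      exp(-(z + exp(-z))) / par[["scale"]]
    },
    stop("unknown family '", family, "'"))
}

## weighted MLE by direct optimization of the weighted log-density;
## parameters are log-transformed (Gumbel location is left free).
## Returns the old parameters if optimization fails to improve.
.wmleFalse <- function(s, w, shape, scale) {
  if (sum(w) < 1e-8) return(c(shape = shape, scale = scale))
  obj <- function(p) -sum(w * log(pmax(.dfalse(s, exp(p[1]), exp(p[2])),
                                       1e-300)))
  cur <- c(log(shape), log(scale))
  fit <- tryCatch(optim(cur, obj, method = "Nelder-Mead"),
                  error = function(e) NULL)
  if (is.null(fit) || fit$value > obj(cur) + 1e-12)
    c(shape = shape, scale = scale)
  else c(shape = exp(fit$par[1]), scale = exp(fit$par[2]))
}

.wmleTrue <- function(s, w, family, par, sMax = 1) {
  if (sum(w) < 1e-8) return(par)
  if (family == "gumbel") {
    obj <- function(p) -sum(w * log(pmax(.dmirror(
      s, family, c(loc = p[1], scale = exp(p[2])), sMax), 1e-300)))
    cur <- c(par[["loc"]], log(par[["scale"]]))
    fit <- tryCatch(optim(cur, obj, method = "Nelder-Mead"),
                    error = function(e) NULL)
    if (is.null(fit) || fit$value > obj(cur) + 1e-12) par
    else c(loc = fit$par[1], scale = exp(fit$par[2]))
  } else {
    obj <- function(p) -sum(w * log(pmax(.dmirror(
      s, family, c(shape = exp(p[1]), scale = exp(p[2])), sMax), 1e-300)))
    cur <- log(c(par[["shape"]], par[["scale"]]))
    fit <- tryCatch(optim(cur, obj, method = "Nelder-Mead"),
                    error = function(e) NULL)
    if (is.null(fit) || fit$value > obj(cur) + 1e-12) par
    else c(shape = exp(fit$par[1]), scale = exp(fit$par[2]))
  }
}

## deterministic method-of-moments initialization: the lower score half
## seeds the false component, the mirrored upper half the true component
.emInit <- function(s, family, sMax) {
  med <- stats::median(s)
  lo <- s[s <= med]; hi <- sMax - s[s > med]
  mom <- function(x) {
    m <- mean(x); v <- max(stats::var(x), 1e-8)
    c(shape = max(m^2 / v, 0.1), scale = max(v / m, 1e-6))
  }
  fpar <- mom(pmax(lo, 1e-4))
  hi <- pmax(hi, 1e-4)
  tpar <- switch(family,
    gamma = mom(hi),
    weibull = {
      cv <- stats::sd(hi) / mean(hi)
      shp <- max(min(cv^(-1.086), 50), 0.2)
      c(shape = shp, scale = mean(hi) / gamma(1 + 1 / shp))
    },
    gumbel = {
      beta <- max(stats::sd(hi) * sqrt(6) / pi, 1e-4)
      c(loc = mean(hi) - 0.5772156649 * beta, scale = beta)
    })
  list(pi0 = 0.5, fpar = fpar, tpar = tpar)
}

#' Fit the two-component empirical-Bayes mixture by EM
#'
#' @param scores numeric vector of best-hit scores of the full
#'   unthresholded query batch; at least 50 values in (0, 1\] are
#'   required (the mixture is unidentifiable on tiny samples).
#' @param trueFamily `"auto"` (default; all three families are fitted and
#'   the best log-likelihood wins), `"gamma"`, `"gumbel"` or `"weibull"`.
#' @param tol EM stops when the log-likelihood improves by less than
#'   `tol`.
#' @param maxIter maximum number of EM iterations; if reached without
#'   convergence the best iterate is returned flagged
#'   (`converged = FALSE`).
#' @param sMax upper bound of the score domain used for mirroring (1 for
#'   cosine-family scores).
#' @return a fitted [MixtureModel-class].
#' @seealso [posteriorErrorProbability()], [estimatePit()], [fdrFromPep()]
#' @export
fitMixtureEM <- function(scores, trueFamily = c("auto", "gamma", "gumbel",
                                                "weibull"),
                         tol = 1e-6, maxIter = 500L, sMax = 1) {
  trueFamily <- match.arg(trueFamily)
  if (length(scores) < 50L)
    stop("empirical-Bayes mixture fit needs at least 50 scores (got ",
         length(scores), "); use the target-decoy estimator instead",
         call. = FALSE)
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > sMax))
    stop("scores must lie in [0, ", sMax, "]", call. = FALSE)
  s <- pmin(pmax(scores, 1e-6), sMax - 1e-6)
  if (trueFamily == "auto") {
    fits <- lapply(c("gamma", "gumbel", "weibull"), function(f)
      tryCatch(fitMixtureEM(scores, f, tol, maxIter, sMax),
               error = function(e) NULL))
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) stop("mixture fit failed for all families")
    ll <- vapply(fits, function(m) m@logLik, numeric(1))
    return(fits[[which.max(ll)]])
  }
  init <- .emInit(s, trueFamily, sMax)
  pi0 <- init$pi0; fpar <- init$fpar; tpar <- init$tpar
  loglik <- function(pi0, fpar, tpar) {
    mix <- pi0 * .dfalse(s, fpar[["shape"]], fpar[["scale"]]) +
      (1 - pi0) * .dmirror(s, trueFamily, tpar, sMax)
    sum(log(pmax(mix, 1e-300)))
  }
  ll <- loglik(pi0, fpar, tpar)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    f0 <- pi0 * .dfalse(s, fpar[["shape"]], fpar[["scale"]])
    f1 <- (1 - pi0) * .dmirror(s, trueFamily, tpar, sMax)
    tot <- pmax(f0 + f1, 1e-300)
    r0 <- f0 / tot
    pi0New <- min(max(mean(r0), 1e-6), 1 - 1e-6)
    fparNew <- .wmleFalse(s, r0, fpar[["shape"]], fpar[["scale"]])
    tparNew <- .wmleTrue(s, 1 - r0, trueFamily, tpar, sMax)
    llNew <- loglik(pi0New, fparNew, tparNew)
    if (llNew + 1e-9 < ll) break   # numerical stall: keep best iterate
    improvement <- llNew - ll
    pi0 <- pi0New; fpar <- fparNew; tpar <- tparNew; ll <- llNew
    trace <- c(trace, ll)
    if (improvement < tol) { converged <- TRUE; break }
  }
  new("MixtureModel", pi0 = pi0, falseShape = unname(fpar[["shape"]]),
      falseScale = unname(fpar[["scale"]]), trueFamily = trueFamily,
      truePar = tpar, logLik = ll, logLikTrace = trace,
      nIter = iter, converged = converged, scoreMax = sMax)
}

#' Posterior error probability of a score under a fitted mixture
#'
#' `PEP(s) = pi0 f0(s) / (pi0 f0(s) + (1 - pi0) f1(s))`: the estimated
#' probability that a single hit with this score is false. Where the total
#' density vanishes the conservative limit 1 is returned.
#'
#' @param model a fitted [MixtureModel-class].
#' @param score numeric vector of scores.
#' @return numeric vector of PEPs in \[0, 1\].
#' @export
posteriorErrorProbability <- function(model, score) {
  f0 <- model@pi0 * .dfalse(pmin(pmax(score, 1e-6),
                                 model@scoreMax - 1e-6),
                            model@falseShape, model@falseScale)
  f1 <- (1 - model@pi0) * .dmirror(pmin(pmax(score, 1e-6),
                                        model@scoreMax - 1e-6),
                                   model@trueFamily, model@truePar,
                                   model@scoreMax)
  tot <- f0 + f1
  ifelse(tot <= 0 | !is.finite(tot), 1, pmin(pmax(f0 / tot, 0), 1))
}

#' Empirical-Bayes FDR and q-values from posterior error probabilities
#'
#' The FDR at a score threshold is the average PEP of all hits with score
#' at or above the threshold; q-values are the running minimum over
#' thresholds, as in [estimateFdrTda()].
#'
#' @param model a fitted [MixtureModel-class].
#' @param hits data.frame of target hits (column `score`), the population
#'   the model was fitted on.
#' @return data.frame sorted by descending score: `query_id` and
#'   `reference_id` when present, `threshold`, `pep`, `fdr`, `q`.
#' @export
fdrFromPep <- function(model, hits) {
  stopifnot(nrow(hits) > 0L)
  ord <- order(-hits$score)
  h <- hits[ord, , drop = FALSE]
  pep <- posteriorErrorProbability(model, h$score)
  fdr <- cumsum(pep) / seq_along(pep)
  q <- rev(cummin(rev(fdr)))
  out <- data.frame(threshold = h$score, pep = pep, fdr = fdr, q = q,
                    stringsAsFactors = FALSE)
  for (col in c("reference_id", "query_id"))
    if (col %in% names(h)) out <- cbind(h[col], out)
  rownames(out) <- NULL
  out
}

#' Percentage of incorrect targets (PIT) from a fitted mixture
#'
#' The PIT is the area under the scaled false-component curve of the
#' mixture fitted to the complete unthresholded batch of target hits; for
#' a normalized component density this area is the mixture weight `pi0`.
#'
#' @param model a fitted [MixtureModel-class].
#' @return PIT in \[0, 1\].
#' @export
estimatePit <- function(model) pi0(model)

#' Serialize mixture-model parameters as JSON
#'
#' @param model a fitted [MixtureModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMixtureModel <- function(model, path) {
  jsonlite::write_json(list(
    pi0 = model@pi0,
    false_component = list(family = "gamma", shape = model@falseShape,
                           scale = model@falseScale),
    true_component = list(family = model@trueFamily,
                          mirrored = TRUE,
                          parameters = as.list(model@truePar)),
    log_likelihood = model@logLik, n_iter = model@nIter,
    converged = model@converged, score_max = model@scoreMax),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
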