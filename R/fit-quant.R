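# VBEM fitter for quantitative traits: the joint four-group model over two
# cohorts and its single-trait two-group special case. The E-step is one
# coordinate-ascent sweep over SNPs (C++ kernel); the M-step and the evidence
# lower bound have closed forms in the variational moments.

#' Fitter options
#'
#' @param maxIter maximum outer (E+M) iterations.
#' @param tol relative lower-bound change declaring convergence.
#' @param varFloor floor applied to variance estimates.
#' @param alphaFloor floor applied to group probabilities before logs.
#' @param verbose print the lower bound each iteration.
#' @return list of class `"FitOptions"`.
#' @export
fitOptions <- function(maxIter = 1000L, tol = 1e-5, varFloor = 1e-10,
                       alphaFloor = 1e-12, verbose = FALSE) {
  stopifnot(maxIter >= 1, tol > 0, varFloor > 0, alphaFloor > 0)
  structure(list(maxIter = as.integer(maxIter), tol = tol,
                 varFloor = varFloor, alphaFloor = alphaFloor,
                 verbose = verbose), class = "FitOptions")
}

# ---- elementary updates (R reference versions; the C++ sweep applies the
# ---- same formulas SNP by SNP) ----

# Slab factor for one SNP and one trait given the residual excluding that
# SNP: s2 = se / (x'x + se/sb), mu = x'r / (x'x + se/sb).
.snpSlabUpdate <- function(xtx, xr, sigma2e, sigma2beta) {
  stopifnot(sigma2e > 0, sigma2beta > 0, xtx >= 0)
  if (xtx == 0) return(c(mu = 0, s2 = sigma2beta))
  denom <- xtx + sigma2e / sigma2beta
  c(mu = xr / denom, s2 = sigma2e / denom)
}

# log evidence gain for gamma = 1 vs gamma = 0 of one slab factor
.evidenceGain <- function(mu, s2, sigma2beta) {
  0.5 * log(s2 / sigma2beta) + mu^2 / (2 * s2)
}

# Four-group posterior of one SNP from the two per-trait evidence gains:
# alpha_l * exp(u1 [l in {10,11}] + u2 [l in {01,11}]), normalized in
# log space.
.groupPosteriorUpdate <- function(u1, u2, logAlpha) {
  if (!is.finite(u1) || !is.finite(u2))
    stop("non-finite evidence term")
  lg <- logAlpha + c(0, u2, u1, u1 + u2)
  w <- exp(lg - max(lg))
  w / sum(w)
}

.inclusion <- function(gpost) {
  if (ncol(gpost) == 4L) {
    cbind(gpost[, 3L] + gpost[, 4L], gpost[, 2L] + gpost[, 4L])
  } else {
    gpost[, 2L, drop = FALSE]
  }
}

# E_q[gamma beta] and Var_q[gamma beta] per SNP/trait
.effMoments <- function(state) {
  pi <- .inclusion(state$gpost)
  m <- pi * state$mu
  v <- pi * (state$mu^2 + state$s2) - m^2
  list(pi = pi, mean = m, var = v)
}

.logFloor <- function(a, floor) {
  a <- pmax(a, floor)
  log(a / sum(a))
}

# ---- ELBO and M-step cores (shared by joint/single via K = ncol(mu)) ----

# rss[k] = ||y_k - X_k E[gamma beta]||^2; xtxList[[k]] = colSums(X_k^2)
.elboQuantCore <- function(state, params, rss, xtxList, nVec) {
  mom <- .effMoments(state)
  K <- ncol(state$mu)
  lik <- 0
  for (k in seq_len(K)) {
    se <- params$sigma2e[k]; sb <- params$sigma2beta[k]
    varTerm <- sum(xtxList[[k]] * mom$var[, k])
    lik <- lik - nVec[k] / 2 * log(2 * pi * se) -
      (rss[k] + varTerm) / (2 * se) +
      sum(mom$pi[, k] * (0.5 * log(state$s2[, k] / sb) -
                           (state$mu[, k]^2 + state$s2[, k]) / (2 * sb) + 0.5))
  }
  g <- state$gpost
  la <- rep(log(params$alpha), each = nrow(g))
  gamTerm <- sum(ifelse(g > 0, g * (la - log(g)), 0))
  lik + gamTerm
}

.mStepQuantCore <- function(state, params, rss, xtxList, nVec, options) {
  mom <- .effMoments(state)
  K <- ncol(state$mu)
  alpha <- pmax(colMeans(state$gpost), options$alphaFloor)
  alpha <- alpha / sum(alpha)
  sigma2beta <- params$sigma2beta
  sigma2e <- params$sigma2e
  for (k in seq_len(K)) {
    w <- sum(mom$pi[, k])
    if (w < 1e-8) {
      warning("all inclusion probabilities ~0; keeping previous sigma2beta")
    } else {
      sigma2beta[k] <- max(
        sum(mom$pi[, k] * (state$mu[, k]^2 + state$s2[, k])) / w,
        options$varFloor)
    }
    sigma2e[k] <- max((rss[k] + sum(xtxList[[k]] * mom$var[, k])) / nVec[k],
                      options$varFloor)
  }
  list(alpha = alpha, sigma2beta = sigma2beta, sigma2e = sigma2e)
}

# residuals y - X E[gamma beta], computed from scratch
.quantResiduals <- function(state, datasets) {
  mom <- .effMoments(state)
  lapply(seq_along(datasets), function(k) {
    d <- datasets[[k]]
    d@phenotype - drop(d@genotypes %*% mom$mean[, k])
  })
}

.initQuantState <- function(p, K, sigma2beta = 1) {
  ng <- if (K == 2L) 4L else 2L
  list(mu = matrix(0, p, K),
       s2 = matrix(sigma2beta, p, K),
       gpost = matrix(1 / ng, p, ng))
}

.initQuantParams <- function(datasets) {
  K <- length(datasets)
  if (K == 2L) alpha <- c(0.99, 0.0033, 0.0033, 0.0034)
  else alpha <- c(0.99, 0.01)
  list(alpha = alpha, sigma2beta = rep(1, K),
       sigma2e = vapply(datasets, function(d) var(d@phenotype) / 2,
                        numeric(1)))
}

.checkQuantInputs <- function(datasets) {
  for (d in datasets) {
    stopifnot(is(d, "GwasDataset"))
    if (d@traitKind != "quantitative")
      stop("expected quantitative-trait datasets")
  }
  ps <- vapply(datasets, function(d) ncol(d@genotypes), integer(1))
  if (length(unique(ps)) != 1L)
    stop("the cohorts must cover the same number of SNPs")
}

# one joint E-step sweep (exposed for tests and property checks); returns
# the updated state plus the maintained residuals
.eStepQuantJoint <- function(state, params, data1, data2, xtxList = NULL) {
  if (is.null(xtxList))
    xtxList <- list(colSums(data1@genotypes^2), colSums(data2@genotypes^2))
  r <- .quantResiduals(state, list(data1, data2))
  sw <- .sweepJoint(data1@genotypes, data2@genotypes,
                    xtxList[[1L]], xtxList[[2L]], r[[1L]], r[[2L]],
                    state$mu, state$s2, state$gpost,
                    .logFloor(params$alpha, 1e-12),
                    params$sigma2e, params$sigma2beta)
  list(mu = sw$mu, s2 = sw$s2, gpost = sw$gpost,
       residuals = list(sw$r1, sw$r2))
}

.eStepQuantSingle <- function(state, params, data, xtx = NULL) {
  if (is.null(xtx)) xtx <- colSums(data@genotypes^2)
  r <- .quantResiduals(state, list(data))[[1L]]
  sw <- .sweepSingle(data@genotypes, xtx, r, state$mu, state$s2,
                     state$gpost, .logFloor(params$alpha, 1e-12),
                     params$sigma2e, params$sigma2beta)
  list(mu = sw$mu, s2 = sw$s2, gpost = sw$gpost, residuals = list(sw$r))
}

.fitQuant <- function(datasets, options) {
  .checkQuantInputs(datasets)
  K <- length(datasets)
  p <- ncol(datasets[[1L]]@genotypes)
  nVec <- vapply(datasets, function(d) nrow(d@genotypes), integer(1))
  xtxList <- lapply(datasets, function(d) colSums(d@genotypes^2))
  params <- .initQuantParams(datasets)
  state <- .initQuantState(p, K, params$sigma2beta[1L])

  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(options$maxIter)) {
    es <- if (K == 2L) {
      .eStepQuantJoint(state, params, datasets[[1L]], datasets[[2L]], xtxList)
    } else {
      .eStepQuantSingle(state, params, datasets[[1L]], xtxList[[1L]])
    }
    state <- list(mu = es$mu, s2 = es$s2, gpost = es$gpost)
    rss <- vapply(es$residuals, function(r) sum(r^2), numeric(1))
    params <- .mStepQuantCore(state, params, rss, xtxList, nVec, options)
    elbo <- .elboQuantCore(state, params, rss, xtxList, nVec)
    if (options$verbose)
      message(sprintf("iter %d: ELBO %.6f", it, elbo))
    trace <- c(trace, elbo)
    if (it > 1L &&
        abs(elbo - trace[it - 1L]) < options$tol * abs(elbo)) {
      converged <- TRUE
      break
    }
  }
  list(state = state, params = params, trace = trace,
       converged = converged, nIter = length(trace))
}

.buildFit <- function(res, datasets, model, traitKind,
                      phi = list(), psi = list(), sigma2e = numeric(0)) {
  pi <- .inclusion(res$state$gpost)
  lfdrMat <- pmin(pmax(1 - pi, 0), 1)
  new("PleioFit",
      model = model, traitKind = traitKind,
      alpha = res$params$alpha,
      sigma2beta = res$params$sigma2beta,
      sigma2e = if (traitKind == "quantitative") res$params$sigma2e
                else sigma2e,
      phi = phi, psi = psi,
      groupPost = res$state$gpost, mu = res$state$mu, s2 = res$state$s2,
      lfdr = lfdrMat, elboTrace = res$trace,
      converged = res$converged, nIter = as.integer(res$nIter),
      centering = list(
        colMeans = lapply(datasets, function(d) d@colMeans),
        phenoMean = vapply(datasets, function(d) d@phenoMean, numeric(1))))
}

#' Fit the joint four-group model to two quantitative-trait cohorts
#'
#' Alternates a coordinate-ascent E-step over the per-SNP variational
#' factors with closed-form M-step updates of the group probabilities, slab
#' variances, and residual variances, until the relative change of the
#' evidence lower bound falls below `options$tol`. The lower bound is
#' non-decreasing across iterations.
#'
#' @param data1,data2 [GwasDataset-class]s over the same p SNPs.
#' @param options a [fitOptions()].
#' @return a [PleioFit-class] with `model = "joint"`.
#' @examples
#' sim <- simulateQuantPair(simConfig(n1 = 150, p = 120, nTest = 10,
#'                                    alpha1 = 0.05, g = 1, seed = 7))
#' fit <- fitPleioQuant(sim$train[[1]], sim$train[[2]])
#' head(lfdr(fit, 1))
#' @export
fitPleioQuant <- function(data1, data2, options = fitOptions()) {
  res <- .fitQuant(list(data1, data2), options)
  .buildFit(res, list(data1, data2), "joint", "quantitative")
}

#' Fit the single-trait two-group model to one quantitative cohort
#'
#' The same variational machinery restricted to one trait with a scalar
#' non-null proportion: the spike-and-slab Bayesian variable selection
#' regression that the joint model reduces to in the absence of a second
#' cohort. Also the building block of the pleiotropy test's null fit.
#'
#' @param data a quantitative [GwasDataset-class].
#' @inheritParams fitPleioQuant
#' @return a [PleioFit-class] with `model = "single"`.
#' @export
fitSingleQuant <- function(data, options = fitOptions()) {
  res <- .fitQuant(list(data), options)
  .buildFit(res, list(data), "single", "quantitative")
}
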