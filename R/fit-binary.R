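# VBEM fitter for case-control traits. The Bernoulli likelihood
# sigma(y_i eta_i) is bounded below by a fixed-curvature quadratic (the
# Bohning bound, curvature a = 1/4, tight at a per-observation location
# psi_i), which turns each E-step into the quantitative sweep on pseudo-data
# with residual precision a, working response y (1 + b) / a, and a covariate
# offset. Outer iterations tighten the bound (psi), refit the fixed-effect
# covariates (phi), sweep the per-SNP factors, and update (alpha,
# sigma2beta); each block weakly increases the double (Bohning + Jensen)
# lower bound.

.BOHNING_A <- 0.25

# overflow-safe log(1 + exp(x))
.log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# Quadratic-bound coefficients at locations psi:
# log sigma(t) >= -a t^2 / 2 + (1 + b) t - c, with equality at t = psi.
.bohningTerms <- function(psi) {
  stopifnot(all(is.finite(psi)))
  a <- .BOHNING_A
  s <- plogis(psi)
  list(a = a,
       b = a * psi - s,
       c = 0.5 * a * psi^2 - s * psi + .log1pexp(psi),
       psi = psi)
}

# bound-maximizing variational locations given the current q: the expected
# margin y_i E_q[eta_i] (y_i^2 = 1)
.updatePsi <- function(y, etaMean) y * etaMean

# fixed-effect covariate update: weighted least squares of the working
# response (with SNP contributions removed) on Z
.updateCovariates <- function(Z, workResp, Xm) {
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    bad <- colnames(Z)[-seq_len(qrz$rank)]
    stop("rank-deficient covariate matrix (columns: ",
         paste(if (length(bad)) bad else "unnamed", collapse = ", "), ")")
  }
  qr.coef(qrz, workResp - Xm)
}

.elboBinaryCore <- function(state, params, datasets, xtxList) {
  mom <- .effMoments(state)
  K <- length(datasets)
  a <- .BOHNING_A
  lik <- 0
  for (k in seq_len(K)) {
    d <- datasets[[k]]
    sb <- params$sigma2beta[k]
    bt <- .bohningTerms(params$psi[[k]])
    etaMean <- drop(d@covariates %*% params$phi[[k]]) +
      drop(d@genotypes %*% mom$mean[, k])
    lik <- lik +
      sum(-a / 2 * etaMean^2 + (1 + bt$b) * d@phenotype * etaMean - bt$c) -
      a / 2 * sum(xtxList[[k]] * mom$var[, k]) +
      sum(mom$pi[, k] * (0.5 * log(state$s2[, k] / sb) -
                           (state$mu[, k]^2 + state$s2[, k]) / (2 * sb) + 0.5))
  }
  g <- state$gpost
  la <- rep(log(params$alpha), each = nrow(g))
  lik + sum(ifelse(g > 0, g * (la - log(g)), 0))
}

.mStepBinaryCore <- function(state, params, options) {
  mom <- .effMoments(state)
  alpha <- pmax(colMeans(state$gpost), options$alphaFloor)
  alpha <- alpha / sum(alpha)
  sigma2beta <- params$sigma2beta
  for (k in seq_len(ncol(state$mu))) {
    w <- sum(mom$pi[, k])
    if (w < 1e-8) {
      warning("all inclusion probabilities ~0; keeping previous sigma2beta")
    } else {
      sigma2beta[k] <- max(
        sum(mom$pi[, k] * (state$mu[, k]^2 + state$s2[, k])) / w,
        options$varFloor)
    }
  }
  params$alpha <- alpha
  params$sigma2beta <- sigma2beta
  params
}

.checkBinaryInputs <- function(datasets) {
  for (d in datasets) {
    stopifnot(is(d, "GwasDataset"))
    if (d@traitKind != "binary") stop("expected binary-trait datasets")
    if (length(unique(d@phenotype)) < 2L)
      stop("phenotype has a single class")
  }
  ps <- vapply(datasets, function(d) ncol(d@genotypes), integer(1))
  if (length(unique(ps)) != 1L)
    stop("the cohorts must cover the same number of SNPs")
}

.initBinaryParams <- function(datasets) {
  K <- length(datasets)
  alpha <- if (K == 2L) c(0.99, 0.0033, 0.0033, 0.0034) else c(0.99, 0.01)
  list(alpha = alpha, sigma2beta = rep(1, K),
       phi = lapply(datasets, function(d) {
         phi <- numeric(ncol(d@covariates))
         phi[1L] <- qlogis(mean(d@phenotype == 1))
         phi
       }),
       psi = lapply(datasets, function(d) numeric(nrow(d@genotypes))))
}

# one binary E-step pass over all variational blocks except (alpha,
# sigma2beta): psi -> phi -> per-SNP sweep on the Bohning pseudo-data
.eStepBinary <- function(state, params, datasets, xtxList = NULL) {
  K <- length(datasets)
  if (is.null(xtxList))
    xtxList <- lapply(datasets, function(d) colSums(d@genotypes^2))
  a <- .BOHNING_A
  mom <- .effMoments(state)
  pseudo <- vector("list", K)
  for (k in seq_len(K)) {
    d <- datasets[[k]]
    Xm <- drop(d@genotypes %*% mom$mean[, k])
    etaMean <- drop(d@covariates %*% params$phi[[k]]) + Xm
    params$psi[[k]] <- .updatePsi(d@phenotype, etaMean)
    bt <- .bohningTerms(params$psi[[k]])
    w <- d@phenotype * (1 + bt$b) / a
    params$phi[[k]] <- .updateCovariates(d@covariates, w, Xm)
    pseudo[[k]] <- w - drop(d@covariates %*% params$phi[[k]]) - Xm
  }
  if (K == 2L) {
    sw <- .sweepJoint(datasets[[1L]]@genotypes, datasets[[2L]]@genotypes,
                      xtxList[[1L]], xtxList[[2L]],
                      pseudo[[1L]], pseudo[[2L]],
                      state$mu, state$s2, state$gpost,
                      .logFloor(params$alpha, 1e-12),
                      c(1 / a, 1 / a), params$sigma2beta)
  } else {
    sw <- .sweepSingle(datasets[[1L]]@genotypes, xtxList[[1L]],
                       pseudo[[1L]], state$mu, state$s2, state$gpost,
                       .logFloor(params$alpha, 1e-12),
                       1 / a, params$sigma2beta)
  }
  list(state = list(mu = sw$mu, s2 = sw$s2, gpost = sw$gpost),
       params = params)
}

.fitBinary <- function(datasets, options) {
  .checkBinaryInputs(datasets)
  K <- length(datasets)
  p <- ncol(datasets[[1L]]@genotypes)
  xtxList <- lapply(datasets, function(d) colSums(d@genotypes^2))
  params <- .initBinaryParams(datasets)
  state <- .initQuantState(p, K, params$sigma2beta[1L])

  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(options$maxIter)) {
    es <- .eStepBinary(state, params, datasets, xtxList)
    state <- es$state
    params <- .mStepBinaryCore(state, es$params, options)
    elbo <- .elboBinaryCore(state, params, datasets, xtxList)
    if (options$verbose) message(sprintf("iter %d: ELBO %.6f", it, elbo))
    trace <- c(trace, elbo)
    if (it > 1L && abs(elbo - trace[it - 1L]) < options$tol * abs(elbo)) {
      converged <- TRUE
      break
    }
  }
  list(state = state, params = params, trace = trace,
       converged = converged, nIter = length(trace))
}

#' Fit the joint four-group model to two case-control cohorts
#'
#' As [fitPleioQuant()] but for -1/+1 disease status with fixed-effect
#' covariates, using the fixed-curvature quadratic bound on the log-sigmoid
#' to obtain conjugate Gaussian coordinate updates. Each outer iteration
#' tightens the bound's per-observation locations, refits the covariate
#' coefficients by weighted least squares, sweeps the per-SNP factors, and
#' updates the group probabilities and slab variances; the resulting double
#' lower bound is non-decreasing.
#'
#' @param data1,data2 binary [GwasDataset-class]s over the same p SNPs.
#' @inheritParams fitPleioQuant
#' @return a [PleioFit-class] with `model = "joint"`.
#' @export
fitPleioBinary <- function(data1, data2, options = fitOptions()) {
  res <- .fitBinary(list(data1, data2), options)
  .buildFit(res, list(data1, data2), "joint", "binary",
            phi = res$params$phi, psi = res$params$psi)
}

#' Fit the single-trait two-group model to one case-control cohort
#'
#' @param data a binary [GwasDataset-class].
#' @inheritParams fitPleioQuant
#' @return a [PleioFit-class] with `model = "single"`.
#' @export
fitSingleBinary <- function(data, options = fitOptions()) {
  res <- .fitBinary(list(data), options)
  .buildFit(res, list(data), "single", "binary",
            phi = res$params$phi, psi = res$params$psi)
}
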