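# Posterior summaries: global FDR selection from local fdrs, risk
# prediction, and the likelihood-ratio test for pleiotropy.

#' Select SNPs under a global FDR bound
#'
#' Direct-posterior-probability selection: lfdrs are ranked in ascending
#' order and the lfdr threshold zeta is raised from zero to the largest
#' value at which the mean lfdr of the selected set — the estimated FDR —
#' stays at or below the target `tau`. All SNPs tied at zeta are included.
#'
#' @param lfdrVec numeric vector of local false discovery rates in [0, 1].
#' @param tau target global FDR bound in (0, 1).
#' @return list with `tau`, `zeta` (realized lfdr threshold, NA when the
#'   selection is empty), `selected` (integer indices), and `estFdr` (mean
#'   lfdr of the selection; 0 when empty).
#' @examples
#' selectGlobalFdr(c(0.1, 0.2, 0.4, 0.9), tau = 0.2) # selects SNPs 1 and 2
#' @export
selectGlobalFdr <- function(lfdrVec, tau) {
  stopifnot(all(lfdrVec >= 0 & lfdrVec <= 1), tau > 0, tau < 1)
  u <- sort(unique(lfdrVec))
  sorted <- sort(lfdrVec)
  csum <- cumsum(sorted)
  sizes <- findInterval(u, sorted) # selection size at threshold u
  means <- csum[sizes] / sizes
  ok <- which(means <= tau)
  if (!length(ok)) {
    return(list(tau = tau, zeta = NA_real_, selected = integer(0),
                estFdr = 0))
  }
  zeta <- u[max(ok)]
  sel <- which(lfdrVec <= zeta)
  list(tau = tau, zeta = zeta, selected = sel,
       estFdr = mean(lfdrVec[sel]))
}

#' Predict phenotypes or case probabilities for new individuals
#'
#' Applies the fitted posterior-mean effects to raw (uncentered) genotypes:
#' for quantitative traits the prediction is
#' `c_k0 + sum_j (x_kj - c_kj) E(gamma_kj beta_kj)` using the training
#' centering constants; for binary traits the linear predictor additionally
#' includes the covariate term `z phi_k` and is mapped to a case probability
#' by the inverse logit.
#'
#' @param object a [PleioFit-class].
#' @param newGenotypes n x p raw dosage matrix with the training column
#'   order.
#' @param trait which trait to predict (1 or 2).
#' @param newCovariates covariate matrix for binary fits (an intercept
#'   column is prepended when missing); defaults to intercept-only.
#' @param type `"response"` (phenotype value or case probability) or
#'   `"link"` (linear predictor, binary only).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
setMethod("predict", "PleioFit",
  function(object, newGenotypes, trait = 1L, newCovariates = NULL,
           type = c("response", "link"), ...) {
    type <- match.arg(type)
    stopifnot(trait %in% seq_len(ncol(object@mu)))
    newGenotypes <- as.matrix(newGenotypes)
    cmeans <- object@centering$colMeans[[trait]]
    if (ncol(newGenotypes) != length(cmeans))
      stop("new genotypes have the wrong number of SNPs")
    eff <- posteriorEffect(object, trait)
    lin <- drop(newGenotypes %*% eff) - sum(cmeans * eff)
    if (object@traitKind == "quantitative")
      return(object@centering$phenoMean[trait] + lin)
    phi <- object@phi[[trait]]
    if (is.null(newCovariates)) {
      Z <- matrix(1, nrow(newGenotypes), 1L)
      if (length(phi) > 1L)
        stop("fit has covariates; supply newCovariates")
    } else {
      Z <- as.matrix(newCovariates)
      if (!all(Z[, 1L] == 1)) Z <- cbind(1, Z)
      if (ncol(Z) != length(phi))
        stop("newCovariates do not match the fitted covariates")
    }
    eta <- drop(Z %*% phi) + lin
    if (type == "link") eta else plogis(eta)
  })

#' Likelihood-ratio test for pleiotropy between two cohorts
#'
#' Tests whether the two traits' association statuses are dependent:
#' H0: `alpha11 = alpha1* x alpha*1` (independence) against the free
#' four-group alternative. Under the independence constraint the joint
#' model factorizes exactly into two single-trait two-group models, so the
#' null is fit as the two separate single-trait fits and the statistic is
#' `lambda = 2 (L_joint - L_1 - L_2)` with the converged lower bounds as
#' likelihood surrogates, clamped at zero and referred to chi-square with
#' one degree of freedom.
#'
#' The statistic is a difference of large lower bounds, so the component
#' fits are run to a much tighter relative tolerance (default 1e-8) than an
#' ordinary fit; with the standard 1e-5 the residual optimization error is
#' of the same order as lambda itself.
#'
#' @param data1,data2 two [GwasDataset-class]s of the same trait kind over
#'   the same SNPs.
#' @param options a [fitOptions()]; note the tighter default tolerance.
#' @param fits optional pre-computed list `list(joint =, single1 =,
#'   single2 =)` of [PleioFit-class]s to reuse.
#' @return a [PleioLrt-class].
#' @export
pleiotropyTest <- function(data1, data2,
                           options = fitOptions(tol = 1e-8),
                           fits = NULL) {
  if (is.null(fits)) {
    stopifnot(is(data1, "GwasDataset"), is(data2, "GwasDataset"))
    if (data1@traitKind != data2@traitKind)
      stop("the two cohorts must share a trait kind")
    if (data1@traitKind == "quantitative") {
      fits <- list(joint = fitPleioQuant(data1, data2, options),
                   single1 = fitSingleQuant(data1, options),
                   single2 = fitSingleQuant(data2, options))
    } else {
      fits <- list(joint = fitPleioBinary(data1, data2, options),
                   single1 = fitSingleBinary(data1, options),
                   single2 = fitSingleBinary(data2, options))
    }
  }
  lastElbo <- function(f) f@elboTrace[length(f@elboTrace)]
  elboAlt <- lastElbo(fits$joint)
  elboNull <- lastElbo(fits$single1) + lastElbo(fits$single2)
  raw <- 2 * (elboAlt - elboNull)
  lambda <- max(raw, 0)
  new("PleioLrt",
      lambda = lambda,
      pValue = pchisq(lambda, df = 1, lower.tail = FALSE),
      elboAlt = elboAlt, elboNull = elboNull,
      alphaAlt = fits$joint@alpha,
      alphaNull = independenceProjection(fits$single1@alpha[2L],
                                         fits$single2@alpha[2L]),
      clamped = raw < 0)
}

#' Per-SNP result table of a fit
#'
#' @param fit a [PleioFit-class].
#' @param variants optional variant table (e.g. from [readPlink()]) whose
#'   `id`, `chrom`, `pos` columns are carried through.
#' @param tau global FDR bound used for the per-trait `selected` flags.
#' @return data.frame with one row per SNP: lfdr, posterior effect, and
#'   selection flag per trait.
#' @export
resultTable <- function(fit, variants = NULL, tau = 0.2) {
  p <- nrow(fit@lfdr)
  K <- ncol(fit@lfdr)
  out <- if (!is.null(variants)) {
    data.frame(id = variants$id, chrom = variants$chrom, pos = variants$pos)
  } else {
    data.frame(id = paste0("snp", seq_len(p)))
  }
  for (k in seq_len(K)) {
    sel <- selectGlobalFdr(fit@lfdr[, k], tau)
    out[[paste0("lfdr", k)]] <- fit@lfdr[, k]
    out[[paste0("effect", k)]] <- posteriorEffect(fit, k)
    out[[paste0("selected", k)]] <- seq_len(p) %in% sel$selected
  }
  out
}
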