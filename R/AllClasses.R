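#' @import methods
#' @importFrom stats var rnorm rbinom runif qnorm quantile pchisq plogis qlogis
#'   rt sd cor aggregate coef predict
#' @importFrom utils read.table write.table
#' @useDynLib pleiogwas, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' GwasDataset: one cohort's genotypes and phenotype
#'
#' Container for a single GWAS cohort after preprocessing: mean-imputed,
#' column-centered genotype dosages, the phenotype (centered for quantitative
#' traits, coded -1/+1 for case-control traits), an optional fixed-effect
#' covariate matrix whose first column is an intercept, and the centering
#' constants (per-SNP dosage means and the phenotype mean before centering)
#' needed later for prediction on raw genotypes.
#'
#' @slot genotypes centered n x p dosage matrix.
#' @slot phenotype length-n numeric; centered values (quantitative) or
#'   -1/+1 labels (binary).
#' @slot covariates n x p0 matrix with a leading all-ones column (binary
#'   traits), or NULL.
#' @slot colMeans length-p dosage means removed from each genotype column.
#' @slot phenoMean phenotype mean removed before centering (0 for binary).
#' @slot traitKind `"quantitative"` or `"binary"`.
#'
#' @seealso [gwasDataset()] for the validating constructor.
#' @export
setClass("GwasDataset",
  representation(
    genotypes = "matrix",
    phenotype = "numeric",
    covariates = "matrixOrNULL",
    colMeans = "numeric",
    phenoMean = "numeric",
    traitKind = "character"
  )
)

setValidity("GwasDataset", function(object) {
  msg <- character()
  n <- nrow(object@genotypes)
  p <- ncol(object@genotypes)
  if (length(object@phenotype) != n)
    msg <- c(msg, "genotype rows and phenotype length disagree")
  if (length(object@colMeans) != p)
    msg <- c(msg, "colMeans length must equal the number of SNPs")
  if (!object@traitKind %in% c("quantitative", "binary"))
    msg <- c(msg, "traitKind must be 'quantitative' or 'binary'")
  if (n > 0 && p > 0) {
    cm <- max(abs(colMeans(object@genotypes)))
    if (cm > 1e-8)
      msg <- c(msg, "genotype columns are not centered")
  }
  if (object@traitKind == "binary") {
    if (!all(object@phenotype %in% c(-1, 1)))
      msg <- c(msg, "binary phenotype must contain only -1 and +1")
    if (is.null(object@covariates))
      msg <- c(msg, "binary datasets require a covariate matrix")
    else if (nrow(object@covariates) != n)
      msg <- c(msg, "covariate rows and genotype rows disagree")
  } else if (n > 1 && abs(mean(object@phenotype)) > 1e-8 * max(1, sd(object@phenotype))) {
    msg <- c(msg, "quantitative phenotype is not centered")
  }
  if (length(msg)) msg else TRUE
})

#' PleioFit: a fitted spike-and-slab variational model
#'
#' Result of fitting either the joint four-group model on two cohorts
#' (`model = "joint"`) or the single-trait two-group model
#' (`model = "single"`). Holds the converged variational state (per-SNP
#' group posteriors, slab means and variances), the estimated model
#' parameters, the evidence-lower-bound trace, per-trait local false
#' discovery rates, and the training centering constants used by
#' [predict()][predict,PleioFit-method].
#'
#' @slot model `"joint"` or `"single"`.
#' @slot traitKind `"quantitative"` or `"binary"`.
#' @slot alpha group probabilities: length 4 (joint, order 00/01/10/11) or
#'   length 2 (single, order null/non-null).
#' @slot sigma2beta slab variances, one per trait.
#' @slot sigma2e residual variances (quantitative traits only; empty for
#'   binary).
#' @slot phi list of covariate coefficient vectors (binary traits only).
#' @slot psi list of per-observation variational locations of the quadratic
#'   bound (binary traits only).
#' @slot groupPost p x 4 (or p x 2) matrix of per-SNP group posteriors.
#' @slot mu,s2 p x K slab means and variances (K = number of traits).
#' @slot lfdr p x K local false discovery rates.
#' @slot elboTrace lower-bound value after each outer iteration.
#' @slot converged,nIter convergence flag and iteration count.
#' @slot centering list with per-trait `colMeans` and `phenoMean` from
#'   training, for prediction on raw genotypes.
#' @export
setClass("PleioFit",
  representation(
    model = "character",
    traitKind = "character",
    alpha = "numeric",
    sigma2beta = "numeric",
    sigma2e = "numeric",
    phi = "list",
    psi = "list",
    groupPost = "matrix",
    mu = "matrix",
    s2 = "matrix",
    lfdr = "matrix",
    elboTrace = "numeric",
    converged = "logical",
    nIter = "integer",
    centering = "list"
  )
)

setValidity("PleioFit", function(object) {
  msg <- character()
  ng <- if (object@model == "joint") 4L else 2L
  if (ncol(object@groupPost) != ng)
    msg <- c(msg, "groupPost has the wrong number of group columns")
  rs <- rowSums(object@groupPost)
  if (length(rs) && max(abs(rs - 1)) > 1e-6)
    msg <- c(msg, "groupPost rows must sum to 1")
  if (any(object@s2 <= 0))
    msg <- c(msg, "slab variances must be positive")
  if (any(object@lfdr < -1e-12 | object@lfdr > 1 + 1e-12))
    msg <- c(msg, "lfdr entries must lie in [0, 1]")
  if (any(object@sigma2beta <= 0))
    msg <- c(msg, "sigma2beta must be positive")
  if (length(msg)) msg else TRUE
})

#' PleioLrt: likelihood-ratio test for pleiotropy
#'
#' @slot lambda test statistic, twice the lower-bound gap between the joint
#'   fit and the independence-constrained fit, clamped at zero.
#' @slot pValue upper chi-square(1) tail probability.
#' @slot elboAlt,elboNull converged lower bounds of the two fits.
#' @slot alphaAlt,alphaNull estimated group probabilities under each
#'   hypothesis (the null vector is the product of the marginals).
#' @slot clamped TRUE when a negative raw statistic was clamped to zero.
#' @export
setClass("PleioLrt",
  representation(
    lambda = "numeric",
    pValue = "numeric",
    elboAlt = "numeric",
    elboNull = "numeric",
    alphaAlt = "numeric",
    alphaNull = "numeric",
    clamped = "logical"
  )
)

setMethod("show", "GwasDataset", function(object) {
  cat(sprintf(
    "GwasDataset: %d samples x %d SNPs (%s trait)\n",
    nrow(object@genotypes), ncol(object@genotypes), object@traitKind
  ))
  if (object@traitKind == "binary") {
    cat(sprintf(
      "  cases: %d, controls: %d, covariates: %d\n",
      sum(object@phenotype == 1), sum(object@phenotype == -1),
      ncol(object@covariates)
    ))
  }
})

setMethod("show", "PleioFit", function(object) {
  cat(sprintf(
    "PleioFit (%s model, %s traits): %d SNPs\n",
    object@model, object@traitKind, nrow(object@groupPost)
  ))
  cat("  alpha:", format(object@alpha, digits = 4), "\n")
  cat(sprintf(
    "  ELBO %.4f after %d iterations (%sconverged)\n",
    object@elboTrace[length(object@elboTrace)], object@nIter,
    if (object@converged) "" else "not "
  ))
})

setMethod("show", "PleioLrt", function(object) {
  cat(sprintf(
    "Pleiotropy LRT: lambda = %.4g, p = %.4g (chi-square, df = 1)%s\n",
    object@lambda, object@pValue,
    if (object@clamped) " [negative statistic clamped to 0]" else ""
  ))
})

# ---- accessors ----

#' @describeIn GwasDataset centered genotype matrix
#' @param x,object a `GwasDataset` or `PleioFit`
#' @export
genotypes <- function(x) x@genotypes

#' @describeIn GwasDataset phenotype vector
#' @export
phenotype <- function(x) x@phenotype

#' @describeIn GwasDataset trait kind
#' @export
traitKind <- function(x) x@traitKind

#' @describeIn GwasDataset covariate matrix (or NULL)
#' @export
covariates <- function(x) x@covariates

#' Local false discovery rates of a fit
#'
#' Returns `1 - sum(alpha_lj, l in L_k)`: one minus the posterior probability
#' that SNP j is associated with trait k, where `L_1 = {10, 11}` and
#' `L_2 = {01, 11}` in the fixed group order (00, 01, 10, 11).
#'
#' @param fit a [PleioFit-class]
#' @param trait 1 or 2 (only 1 for single-trait fits); NULL returns the
#'   full matrix.
#' @return numeric vector of length p (or a p x K matrix).
#' @export
lfdr <- function(fit, trait = NULL) {
  stopifnot(is(fit, "PleioFit"))
  if (is.null(trait)) return(fit@lfdr)
  stopifnot(trait %in% seq_len(ncol(fit@lfdr)))
  fit@lfdr[, trait]
}

#' Posterior-mean effect sizes
#'
#' The model-based effect of SNP j on trait k, `E(gamma_kj beta_kj)`:
#' the posterior inclusion probability times the slab mean.
#'
#' @inheritParams lfdr
#' @return numeric vector of length p.
#' @export
posteriorEffect <- function(fit, trait = 1L) {
  stopifnot(is(fit, "PleioFit"), trait %in% seq_len(ncol(fit@mu)))
  (1 - fit@lfdr[, trait]) * fit@mu[, trait]
}

#' @describeIn lfdr lower-bound trace over outer iterations
#' @export
elboTrace <- function(fit) fit@elboTrace

#' Estimated model parameters of a fit
#'
#' @inheritParams lfdr
#' @return a list with `alpha`, `sigma2beta`, and `sigma2e` (quantitative)
#'   or `phi`, `psi` (binary).
#' @export
modelParams <- function(fit) {
  stopifnot(is(fit, "PleioFit"))
  out <- list(alpha = fit@alpha, sigma2beta = fit@sigma2beta)
  if (fit@traitKind == "quantitative") out$sigma2e <- fit@sigma2e
  else { out$phi <- fit@phi; out$psi <- fit@psi }
  out
}
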