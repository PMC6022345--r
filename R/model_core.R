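# Group order (00, 01, 10, 11) is fixed package-wide: trait 1 is non-null in
# groups {10, 11}, trait 2 in {01, 11}. All four-group code indexes this order.
.GROUPS <- c("00", "01", "10", "11")
.TRAIT1_GROUPS <- c(3L, 4L) # columns of (10, 11)
.TRAIT2_GROUPS <- c(2L, 4L) # columns of (01, 11)

.checkSimplex <- function(alpha, n = 4L, tol = 1e-8) {
  stopifnot(length(alpha) == n, all(is.finite(alpha)))
  if (any(alpha < -tol) || abs(sum(alpha) - 1) > tol)
    stop("group probabilities must be a simplex (nonnegative, summing to 1)")
  invisible(alpha)
}

#' Build a GwasDataset: impute, center, and code one cohort
#'
#' Mean-imputes missing dosages per SNP, centers every genotype column
#' (storing the removed means), and prepares the phenotype: quantitative
#' phenotypes are centered with the mean stored; binary phenotypes given as
#' 0/1 (or already -1/+1) are coded -1/+1 and left uncentered. For binary
#' traits a covariate matrix with a leading intercept column is attached
#' (an intercept-only matrix is created when none is supplied).
#'
#' @param genotypes n x p dosage matrix with values in \{0, 1, 2\} or NA
#'   (already-centered real values are also accepted and recentered, which
#'   leaves them unchanged).
#' @param phenotype length-n numeric vector; for binary traits, 0/1 or -1/+1
#'   labels.
#' @param traitKind `"quantitative"` or `"binary"`.
#' @param covariates optional n x p0 matrix of fixed-effect covariates for
#'   binary traits; an intercept column is prepended when absent.
#' @return a [GwasDataset-class].
#' @examples
#' d <- gwasDataset(matrix(c(0, 1, 2, 2, 1, 0), 3, 2), c(1.2, -0.5, 3.1))
#' colMeans(genotypes(d)) # all zero
#' @export
gwasDataset <- function(genotypes, phenotype,
                        traitKind = c("quantitative", "binary"),
                        covariates = NULL) {
  traitKind <- match.arg(traitKind)
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  if (length(phenotype) != nrow(genotypes))
    stop("phenotype length must match the number of genotype rows")
  if (length(unique(phenotype[!is.na(phenotype)])) < 2L)
    stop("phenotype has a single distinct value")

  # mean-impute missing dosages per column, then center
  nas <- which(is.na(genotypes))
  if (length(nas)) {
    cm <- colMeans(genotypes, na.rm = TRUE)
    genotypes[nas] <- cm[(nas - 1L) %/% nrow(genotypes) + 1L]
  }
  cmeans <- colMeans(genotypes)
  const <- which(apply(genotypes, 2L, function(x) all(x == x[1L])))
  if (length(const))
    warning(sprintf("%d constant genotype column(s) retained (zero after centering)",
                    length(const)))
  genotypes <- sweep(genotypes, 2L, cmeans)

  if (traitKind == "quantitative") {
    pmean <- mean(phenotype)
    phenotype <- phenotype - pmean
    covariates <- NULL
  } else {
    if (all(phenotype %in% c(0, 1))) phenotype <- 2 * phenotype - 1
    if (!all(phenotype %in% c(-1, 1)))
      stop("binary phenotype must be coded 0/1 or -1/+1")
    pmean <- 0
    if (is.null(covariates)) {
      covariates <- matrix(1, nrow(genotypes), 1L,
                           dimnames = list(NULL, "intercept"))
    } else {
      covariates <- as.matrix(covariates)
      if (!all(covariates[, 1L] == 1))
        covariates <- cbind(intercept = 1, covariates)
    }
  }
  new("GwasDataset",
      genotypes = genotypes, phenotype = as.numeric(phenotype),
      covariates = covariates, colMeans = cmeans, phenoMean = pmean,
      traitKind = traitKind)
}

#' Marginal non-null probabilities of a four-group vector
#'
#' For `alpha = (a00, a01, a10, a11)` returns the per-trait marginal
#' probabilities of association, `a1* = a10 + a11` and `a*1 = a01 + a11`.
#'
#' @param alpha length-4 simplex in the fixed order (00, 01, 10, 11).
#' @return named numeric vector `c(alpha1star, alphaStar1)`.
#' @examples
#' marginalProbs(c(0.9, 0.04, 0.04, 0.02)) # 0.06 0.06
#' @export
marginalProbs <- function(alpha) {
  .checkSimplex(alpha)
  c(alpha1star = alpha[3L] + alpha[4L], alphaStar1 = alpha[2L] + alpha[4L])
}

#' Four-group vector under independent association statuses
#'
#' Maps a pair of marginal association probabilities (a, b) to the
#' four-group vector `((1-a)(1-b), (1-a)b, a(1-b), ab)` — the null of the
#' pleiotropy test, under which the two traits' statuses are independent.
#'
#' @param alpha1star,alphaStar1 marginal non-null probabilities in [0, 1].
#' @return length-4 simplex in the order (00, 01, 10, 11).
#' @examples
#' independenceProjection(0.5, 0.5) # uniform
#' @export
independenceProjection <- function(alpha1star, alphaStar1) {
  a <- alpha1star; b <- alphaStar1
  stopifnot(length(a) == 1L, length(b) == 1L, a >= 0, a <= 1, b >= 0, b <= 1)
  c(`00` = (1 - a) * (1 - b), `01` = (1 - a) * b,
    `10` = a * (1 - b), `11` = a * b)
}
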