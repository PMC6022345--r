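# Synthetic two-cohort GWAS generator: AR-correlated latent Gaussians
# discretized to Hardy-Weinberg dosages, four-group association statuses with
# pleiotropy level g, Gaussian (or heavy-tailed) effect sizes, noise scaled to
# a target heritability, and liability-threshold case-control sampling.

# round-half-up: the design counts (p * alpha1, overlap) are real numbers and
# the half-integer case must round up (e.g. 0.5 shared SNPs -> 1), which base
# round() (round-half-even) would not do.
.roundHalfUp <- function(x) floor(x + 0.5)

# independent sub-streams per logical component so that e.g. changing g never
# perturbs the genotype draw
.subSeeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulation configuration
#'
#' Collects and validates the generative settings of the built-in two-cohort
#' simulator. Defaults are the reference design: two cohorts of 3000 samples,
#' 20,000 SNPs with AR(rho = 0.5) linkage disequilibrium and minor allele
#' frequencies uniform on [0.05, 0.5], a per-trait non-null proportion
#' alpha1 of 0.005 (quantitative) or 0.0025 (binary), heritability 0.5,
#' standard-normal effect sizes, and for binary traits a liability threshold
#' at population prevalence 0.1 with equal numbers of cases and controls.
#'
#' @param n1,n2 training sample sizes per cohort.
#' @param nTest held-out test samples per cohort.
#' @param p number of SNPs.
#' @param rho autoregressive correlation of the latent genotype process,
#'   in [0, 1).
#' @param mafLow,mafHigh bounds of the uniform minor-allele-frequency law.
#' @param alpha1 per-trait non-null proportion (ignored when `alpha` given).
#' @param g pleiotropy level in [0, 1]: 0 = independent statuses,
#'   1 = fully shared non-null sets.
#' @param h2 target heritability in (0, 1) (liability scale for binary).
#' @param traitKind `"quantitative"` or `"binary"`.
#' @param prevalence population disease rate (binary).
#' @param caseControlRatio cases per control in the retained sample (binary).
#' @param effectLaw `"normal"`, `"truncated-normal"` (standard normal
#'   truncated to \[-2, 2\]) or `"t"` (Student t, 4 df) for the effect sizes.
#' @param alpha optional explicit four-group vector (00, 01, 10, 11)
#'   overriding `alpha1`/symmetry, e.g. for asymmetric type-I-error designs.
#' @param seed master seed; all component streams derive from it.
#' @return a validated list of class `"SimConfig"`.
#' @export
simConfig <- function(n1 = 3000L, n2 = n1, nTest = 500L, p = 20000L,
                      rho = 0.5, mafLow = 0.05, mafHigh = 0.5,
                      alpha1 = if (traitKind == "binary") 0.0025 else 0.005,
                      g = 0.5, h2 = 0.5,
                      traitKind = c("quantitative", "binary"),
                      prevalence = 0.1, caseControlRatio = 1,
                      effectLaw = c("normal", "truncated-normal", "t"),
                      alpha = NULL, seed = 1L) {
  traitKind <- match.arg(traitKind)
  effectLaw <- match.arg(effectLaw)
  stopifnot(
    n1 >= 2, n2 >= 2, p >= 2, rho >= 0, rho < 1,
    mafLow > 0, mafLow <= mafHigh, mafHigh <= 0.5,
    alpha1 > 0, alpha1 < 1, g >= 0, g <= 1, h2 > 0, h2 < 1,
    prevalence > 0, prevalence < 1, caseControlRatio > 0
  )
  if (!is.null(alpha)) .checkSimplex(alpha)
  structure(
    list(n1 = as.integer(n1), n2 = as.integer(n2), nTest = as.integer(nTest),
         p = as.integer(p), rho = rho, mafLow = mafLow, mafHigh = mafHigh,
         alpha1 = alpha1, g = g, h2 = h2, traitKind = traitKind,
         prevalence = prevalence, caseControlRatio = caseControlRatio,
         effectLaw = effectLaw, alpha = alpha, seed = as.integer(seed)),
    class = "SimConfig"
  )
}

#' Sample AR-correlated Hardy-Weinberg genotypes
#'
#' Draws n latent rows from a standard-Gaussian AR(rho) process over p sites
#' and discretizes column j at the standard-normal quantiles of
#' `(1 - f_j)^2` and `(1 - f_j)^2 + 2 f_j (1 - f_j)`, so the dosages 0/1/2
#' (minor-allele counts) follow Hardy-Weinberg proportions with minor allele
#' frequency `f_j ~ Uniform(mafLow, mafHigh)`.
#'
#' @param n,p sample and SNP counts.
#' @param rho autoregressive correlation in [0, 1).
#' @param mafLow,mafHigh MAF bounds (ignored when `maf` supplied).
#' @param maf optional length-p vector of fixed MAFs.
#' @param seed optional seed (omit to use the current RNG state).
#' @return list with `genotypes` (n x p, values in 0/1/2) and `maf`.
#' @export
sampleGenotypes <- function(n, p, rho, mafLow = 0.05, mafHigh = 0.5,
                            maf = NULL, seed = NULL) {
  if (rho >= 1) stop("rho must be < 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(maf)) maf <- runif(p, mafLow, mafHigh)
  stopifnot(length(maf) == p, all(maf > 0), all(maf <= 0.5))
  Z <- matrix(rnorm(n * p), n, p)
  if (rho > 0) {
    sc <- sqrt(1 - rho^2)
    for (j in 2:p) Z[, j] <- rho * Z[, j - 1L] + sc * Z[, j]
  }
  q0 <- (1 - maf)^2            # P(0 copies)
  q1 <- q0 + 2 * maf * (1 - maf) # P(0 or 1 copy)
  t0 <- qnorm(q0); t1 <- qnorm(q1)
  G <- (Z > rep(t0, each = n)) + (Z > rep(t1, each = n))
  storage.mode(G) <- "double"
  list(genotypes = G, maf = maf)
}

#' Sample two traits' association statuses with pleiotropy level g
#'
#' Trait 1 receives exactly `round(p * alpha1)` non-null SNPs placed
#' uniformly at random; trait 2 receives the same number, of which
#' `round(p * alpha1 * (alpha1 + g * (1 - alpha1)))` are drawn from trait 1's
#' non-null set (the expected overlap under the four-group law, interpolating
#' from independence at g = 0 to full sharing at g = 1) and the remainder
#' from its null set. Counts round half up. An explicit four-group `alpha`
#' overrides the symmetric design: the per-trait counts are then
#' `round(p * a1*)`, `round(p * a*1)` with overlap `round(p * a11)`.
#'
#' @inheritParams sampleGenotypes
#' @param alpha1 per-trait non-null proportion.
#' @param g pleiotropy level in [0, 1].
#' @param alpha optional explicit four-group probability vector.
#' @return p x 2 binary matrix of association statuses.
#' @export
sampleAssociation <- function(p, alpha1, g, alpha = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(alpha)) {
    n1 <- .roundHalfUp(p * alpha1)
    n2 <- n1
    nShared <- .roundHalfUp(p * alpha1 * (alpha1 + g * (1 - alpha1)))
  } else {
    .checkSimplex(alpha)
    m <- marginalProbs(alpha)
    n1 <- .roundHalfUp(p * m[1L])
    n2 <- .roundHalfUp(p * m[2L])
    nShared <- .roundHalfUp(p * alpha[4L])
  }
  if (n1 < 1L) stop("round(p * alpha1) must be at least 1")
  if (nShared > min(n1, n2))
    stop("requested overlap exceeds a trait's non-null count")
  if (n2 - nShared > p - n1)
    stop("requested non-overlap exceeds the null set")
  gamma <- matrix(0L, p, 2L)
  idx1 <- sample.int(p, n1)
  shared <- if (nShared > 0) sample(idx1, nShared) else integer()
  own2 <- if (n2 - nShared > 0) {
    sample(setdiff(seq_len(p), idx1), n2 - nShared)
  } else integer()
  gamma[idx1, 1L] <- 1L
  gamma[c(shared, own2), 2L] <- 1L
  gamma
}

.sampleEffects <- function(p, law) {
  switch(law,
    "normal" = rnorm(p),
    "truncated-normal" = {
      x <- rnorm(p)
      while (any(bad <- abs(x) > 2)) x[bad] <- rnorm(sum(bad))
      x
    },
    "t" = rt(p, df = 4)
  )
}

# noise variance giving plug-in heritability h2 against the realized sample
# variance of the genetic signal
.noiseVarFor <- function(signal, h2) {
  vs <- var(signal)
  if (vs == 0 && h2 > 0) stop("zero genetic signal with positive h2")
  vs * (1 - h2) / h2
}

#' Simulate a pair of quantitative-trait cohorts
#'
#' Generates two independent cohorts over the same p SNPs (shared MAFs, same
#' AR(rho) LD law), four-group association statuses at pleiotropy level
#' `config$g`, effect sizes from `config$effectLaw`, and phenotypes
#' `y_k = X_k (beta_k * gamma_k) + e_k` with the noise variance set from the
#' realized signal variance so the plug-in heritability equals `config$h2`
#' exactly. A test cohort of `config$nTest` samples per trait is drawn from
#' the same model (same effects and noise variance, fresh genotypes).
#'
#' @param config a [simConfig()] with `traitKind = "quantitative"`.
#' @return list with `train` (two [GwasDataset-class]s), `test` (raw
#'   genotype/phenotype lists), and `truth` (`gamma`, `beta`, `sigma2e`,
#'   `maf`).
#' @export
simulateQuantPair <- function(config) {
  stopifnot(inherits(config, "SimConfig"),
            config$traitKind == "quantitative")
  ss <- .subSeeds(config$seed, 4L) # genotypes, statuses, effects, noise
  p <- config$p

  set.seed(ss[2L])
  gamma <- sampleAssociation(p, config$alpha1, config$g, config$alpha)
  set.seed(ss[3L])
  beta <- matrix(.sampleEffects(2L * p, config$effectLaw), p, 2L) * gamma
  if (all(gamma == 0)) stop("no non-null SNPs: cannot target h2 > 0")

  set.seed(ss[1L])
  maf <- runif(p, config$mafLow, config$mafHigh)
  ns <- c(config$n1, config$n2)
  Xtr <- lapply(ns, function(n) {
    sampleGenotypes(n, p, config$rho, maf = maf)$genotypes
  })
  Xte <- lapply(1:2, function(k) {
    sampleGenotypes(config$nTest, p, config$rho, maf = maf)$genotypes
  })

  set.seed(ss[4L])
  sigma2e <- numeric(2L)
  train <- vector("list", 2L)
  test <- vector("list", 2L)
  for (k in 1:2) {
    sig <- drop(Xtr[[k]] %*% beta[, k])
    sigma2e[k] <- .noiseVarFor(sig, config$h2)
    y <- sig + rnorm(ns[k], sd = sqrt(sigma2e[k]))
    train[[k]] <- gwasDataset(Xtr[[k]], y, "quantitative")
    yTest <- drop(Xte[[k]] %*% beta[, k]) +
      rnorm(config$nTest, sd = sqrt(sigma2e[k]))
    test[[k]] <- list(genotypes = Xte[[k]], phenotype = yTest)
  }
  list(train = train, test = test,
       truth = list(gamma = gamma, beta = beta, sigma2e = sigma2e, maf = maf))
}

# Draw one case-control cohort under the liability model: liability
# l = X (zeta * gamma) + e exceeding `thresh` marks a case; oversample the
# population until nCase cases and nControl controls are retained.
.sampleLiabilityCohort <- function(n, p, rho, maf, zeta, sigma2e, prevalence,
                                   caseControlRatio, thresh) {
  nCase <- .roundHalfUp(n * caseControlRatio / (1 + caseControlRatio))
  nControl <- n - nCase
  Xc <- matrix(0, n, p)
  y <- integer(n)
  gotCase <- 0L; gotControl <- 0L
  drawn <- 0L; popCases <- 0L
  maxDraws <- ceiling(60 * n / min(prevalence, 1 - prevalence))
  batch <- max(200L, ceiling(n / prevalence / 4))
  while (gotCase < nCase || gotControl < nControl) {
    if (drawn >= maxDraws)
      stop("insufficient cases/controls within the oversampling budget")
    Xb <- sampleGenotypes(batch, p, rho, maf = maf)$genotypes
    lb <- drop(Xb %*% zeta) + rnorm(batch, sd = sqrt(sigma2e))
    isCase <- lb > thresh
    drawn <- drawn + batch
    popCases <- popCases + sum(isCase)
    needC <- which(isCase)[seq_len(min(sum(isCase), nCase - gotCase))]
    needU <- which(!isCase)[seq_len(min(sum(!isCase), nControl - gotControl))]
    if (length(needC)) {
      Xc[gotCase + seq_along(needC), ] <- Xb[needC, , drop = FALSE]
      y[gotCase + seq_along(needC)] <- 1L
      gotCase <- gotCase + length(needC)
    }
    if (length(needU)) {
      Xc[nCase + gotControl + seq_along(needU), ] <- Xb[needU, , drop = FALSE]
      gotControl <- gotControl + length(needU)
    }
  }
  ord <- sample.int(n) # shuffle case/control blocks
  list(genotypes = Xc[ord, , drop = FALSE], phenotype = y[ord],
       popCaseFrac = popCases / drawn)
}

#' Simulate a pair of case-control cohorts under the liability model
#'
#' Liabilities `l = X (zeta * gamma) + e` use the same four-group statuses
#' and effect-size law as the quantitative generator, with the noise variance
#' targeting `config$h2` on the liability scale. Disease status is liability
#' above the `(1 - prevalence)` population quantile (estimated from an
#' auxiliary population draw of 10x the cohort size, capped at 50,000);
#' the population is then oversampled and cases/controls retained at
#' `config$caseControlRatio`. Covariates are an intercept column.
#'
#' @param config a [simConfig()] with `traitKind = "binary"`.
#' @return as [simulateQuantPair()]; `truth` gains `popCaseFrac`, the
#'   realized population case fraction per cohort.
#' @export
simulateBinaryPair <- function(config) {
  stopifnot(inherits(config, "SimConfig"), config$traitKind == "binary")
  ss <- .subSeeds(config$seed, 4L) # maf, statuses, effects, sampling
  p <- config$p

  set.seed(ss[2L])
  gamma <- sampleAssociation(p, config$alpha1, config$g, config$alpha)
  set.seed(ss[3L])
  zeta <- matrix(.sampleEffects(2L * p, config$effectLaw), p, 2L) * gamma
  if (all(gamma == 0)) stop("no non-null SNPs: cannot target h2 > 0")

  set.seed(ss[1L])
  maf <- runif(p, config$mafLow, config$mafHigh)

  set.seed(ss[4L])
  ns <- c(config$n1, config$n2)
  train <- vector("list", 2L)
  test <- vector("list", 2L)
  popCaseFrac <- numeric(2L)
  for (k in 1:2) {
    # one auxiliary population draw (10x the cohort, capped) per cohort sets
    # both the noise variance targeting liability-scale h2 and the
    # (1 - prevalence) liability threshold
    aux <- sampleGenotypes(min(10L * ns[k], 50000L), p, config$rho,
                           maf = maf)$genotypes
    sig <- drop(aux %*% zeta[, k])
    sigVar <- var(sig)
    if (sigVar == 0) stop("zero genetic signal with positive h2")
    sigma2e <- sigVar * (1 - config$h2) / config$h2
    lAux <- sig + rnorm(length(sig), sd = sqrt(sigma2e))
    thresh <- quantile(lAux, 1 - config$prevalence, names = FALSE)
    coh <- .sampleLiabilityCohort(ns[k], p, config$rho, maf, zeta[, k],
                                  sigma2e, config$prevalence,
                                  config$caseControlRatio, thresh)
    train[[k]] <- gwasDataset(coh$genotypes, coh$phenotype, "binary")
    popCaseFrac[k] <- coh$popCaseFrac
    te <- .sampleLiabilityCohort(config$nTest, p, config$rho, maf, zeta[, k],
                                 sigma2e, config$prevalence,
                                 config$caseControlRatio, thresh)
    test[[k]] <- list(genotypes = te$genotypes, phenotype = te$phenotype)
  }
  list(train = train, test = test,
       truth = list(gamma = gamma, beta = zeta, maf = maf,
                    popCaseFrac = popCaseFrac))
}

#' @export
print.SimConfig <- function(x, ...) {
  cat(sprintf(
    "SimConfig: %s traits, n = (%d, %d) + %d test, p = %d\n",
    x$traitKind, x$n1, x$n2, x$nTest, x$p))
  cat(sprintf(
    "  rho = %g, MAF ~ U[%g, %g], alpha1 = %g, g = %g, h2 = %g, seed = %d\n",
    x$rho, x$mafLow, x$mafHigh, x$alpha1, x$g, x$h2, x$seed))
  if (x$traitKind == "binary")
    cat(sprintf("  prevalence = %g, case:control = %g\n",
                x$prevalence, x$caseControlRatio))
  invisible(x)
}
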