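# Shared fixtures and independent oracles used across the suite.

# mean-zero matrix with exactly orthonormal columns (times `scale`): the
# column space of a centered matrix is orthogonal to the ones vector, so a
# QR basis of it keeps zero column means
orthoCentered <- function(n, p, scale = 3) {
  M <- matrix(rnorm(n * p), n, p)
  M <- sweep(M, 2, colMeans(M))
  qr.Q(qr(M)) * scale
}

# exact log N(y; 0, se I + sb X_g X_g') for one association configuration
.logLikGamma <- function(y, X, gam, se, sb) {
  Xg <- X[, gam == 1, drop = FALSE]
  S <- diag(se, length(y)) + sb * tcrossprod(Xg)
  -0.5 * (length(y) * log(2 * pi) + as.numeric(determinant(S)$modulus) +
            drop(crossprod(y, solve(S, y))))
}

# brute-force posterior over all 4^p joint association configurations:
# per-SNP group posteriors and the exact log marginal likelihood
enumJointQuant <- function(y1, X1, y2, X2, params) {
  p <- ncol(X1)
  configs <- as.matrix(expand.grid(rep(list(0:1), p)))
  nc <- nrow(configs)
  lp <- matrix(NA_real_, nc, nc)
  ll1 <- apply(configs, 1, function(g) {
    .logLikGamma(y1, X1, g, params$sigma2e[1], params$sigma2beta[1])
  })
  ll2 <- apply(configs, 1, function(g) {
    .logLikGamma(y2, X2, g, params$sigma2e[2], params$sigma2beta[2])
  })
  for (i in seq_len(nc)) for (j in seq_len(nc)) {
    labs <- configs[i, ] * 2 + configs[j, ] + 1 # group index in (00,01,10,11)
    lp[i, j] <- ll1[i] + ll2[j] + sum(log(params$alpha[labs]))
  }
  m <- max(lp)
  logMarg <- m + log(sum(exp(lp - m)))
  w <- exp(lp - logMarg)
  gpost <- matrix(0, p, 4)
  for (i in seq_len(nc)) for (j in seq_len(nc)) {
    labs <- configs[i, ] * 2 + configs[j, ] + 1
    for (s in seq_len(p)) gpost[s, labs[s]] <- gpost[s, labs[s]] + w[i, j]
  }
  list(gpost = gpost, logMarg = logMarg)
}

# single-trait version over 2^p configurations
enumSingleQuant <- function(y, X, alpha1, se, sb) {
  p <- ncol(X)
  configs <- as.matrix(expand.grid(rep(list(0:1), p)))
  lp <- apply(configs, 1, function(g) {
    .logLikGamma(y, X, g, se, sb) +
      sum(log(ifelse(g == 1, alpha1, 1 - alpha1)))
  })
  m <- max(lp)
  logMarg <- m + log(sum(exp(lp - m)))
  w <- exp(lp - logMarg)
  list(pip = unname(colSums(configs * w)), logMarg = logMarg)
}

# exact log marginal of the binary model at fixed (alpha, sigma2beta, phi)
# for p = 1 SNP per trait, by enumeration over the four group labels and
# numeric integration over each slab effect
enumBinaryLogMarg <- function(d1, d2, alpha, sigma2beta, phi) {
  margOne <- function(d, gam, sb, ph) {
    base <- drop(d@covariates %*% ph)
    x <- d@genotypes[, 1]
    y <- d@phenotype
    if (gam == 0) {
      return(sum(plogis(y * base, log.p = TRUE)))
    }
    f <- function(b) {
      vapply(b, function(bi) {
        exp(sum(plogis(y * (base + bi * x), log.p = TRUE)) +
              dnorm(bi, 0, sqrt(sb), log = TRUE))
      }, numeric(1))
    }
    log(integrate(f, -Inf, Inf, rel.tol = 1e-10)$value)
  }
  lp <- numeric(4)
  k <- 1
  for (g1 in 0:1) for (g2 in 0:1) {
    lab <- g1 * 2 + g2 + 1
    lp[k] <- log(alpha[lab]) +
      margOne(d1, g1, sigma2beta[1], phi[[1]]) +
      margOne(d2, g2, sigma2beta[2], phi[[2]])
    k <- k + 1
  }
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# small random quantitative instance (not necessarily orthogonal)
smallQuantPair <- function(seed, n = 80, p = 50, alpha1 = 0.06, g = 1,
                           h2 = 0.5) {
  simulateQuantPair(simConfig(n1 = n, p = p, nTest = 10, alpha1 = alpha1,
                              g = g, h2 = h2, seed = seed))
}

smallBinaryPair <- function(seed, n = 80, p = 50, alpha1 = 0.06, g = 1,
                            h2 = 0.5) {
  simulateBinaryPair(simConfig(n1 = n, p = p, nTest = 10, alpha1 = alpha1,
                               g = g, h2 = h2, seed = seed,
                               traitKind = "binary"))
}

lastElbo <- function(fit) fit@elboTrace[length(fit@elboTrace)]

expectMonotone <- function(trace, tol = 1e-8) {
  expect_true(all(diff(trace) >= -tol * pmax(1, abs(trace[-1]))))
}

# quantitative ELBO of a (state, params) pair on two datasets, residuals
# recomputed from scratch (test-side wrapper around the package internals)
elboQuantOf <- function(state, params, d1, d2) {
  xtxList <- list(colSums(d1@genotypes^2), colSums(d2@genotypes^2))
  r <- pleiogwas:::.quantResiduals(state, list(d1, d2))
  rss <- vapply(r, function(x) sum(x^2), numeric(1))
  pleiogwas:::.elboQuantCore(state, params, rss, xtxList,
                             c(nrow(d1@genotypes), nrow(d2@genotypes)))
}
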