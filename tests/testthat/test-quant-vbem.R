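test_that("the slab update maximizes the per-coordinate bound", {
  # no signal and constant-SNP edge cases
  expect_equal(pleiogwas:::.snpSlabUpdate(4, 0, 1, 2), c(mu = 0, s2 = 1 / 4.5))
  expect_equal(pleiogwas:::.snpSlabUpdate(0, 0, 1, 2), c(mu = 0, s2 = 2))

  # numeric-optimizer oracle: the per-coordinate ELBO contribution of one
  # slab factor (given gamma = 1) is
  #   -(xtx (mu^2 + s2) - 2 mu xr) / (2 se) - (mu^2 + s2) / (2 sb)
  #   + 0.5 log(s2)
  set.seed(3)
  for (i in 1:5) {
    xtx <- runif(1, 0.5, 5); xr <- rnorm(1, 0, 3)
    se <- runif(1, 0.3, 2); sb <- runif(1, 0.3, 2)
    f <- function(par) {
      mu <- par[1]; s2 <- exp(par[2])
      -(-(xtx * (mu^2 + s2) - 2 * mu * xr) / (2 * se) -
          (mu^2 + s2) / (2 * sb) + 0.5 * log(s2))
    }
    opt <- optim(c(0, 0), f, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 500))
    cf <- pleiogwas:::.snpSlabUpdate(xtx, xr, se, sb)
    expect_equal(unname(cf["mu"]), opt$par[1], tolerance = 1e-6)
    expect_equal(unname(cf["s2"]), exp(opt$par[2]), tolerance = 1e-6)
  }
})

test_that("the group posterior is the prior-weighted softmax of the evidence gains", {
  unif <- log(rep(0.25, 4))
  expect_equal(pleiogwas:::.groupPosteriorUpdate(0, 0, unif), rep(0.25, 4))
  # u1 = 1, u2 = 0 at a uniform prior: softmax of (0, 0, 1, 1)
  w <- exp(c(0, 0, 1, 1)); w <- w / sum(w)
  expect_equal(pleiogwas:::.groupPosteriorUpdate(1, 0, unif), w,
               tolerance = 1e-12)
  expect_equal(round(w, 3), c(0.134, 0.134, 0.366, 0.366))
  # overwhelming trait-1 evidence concentrates on {10, 11} equally
  big <- pleiogwas:::.groupPosteriorUpdate(500, 0, unif)
  expect_equal(big, c(0, 0, 0.5, 0.5), tolerance = 1e-12)
  expect_error(pleiogwas:::.groupPosteriorUpdate(NaN, 0, unif), "non-finite")
})

test_that("converged variational posteriors equal exact enumeration on orthogonal designs", {
  set.seed(42)
  n <- 12; p <- 3
  X1 <- orthoCentered(n, p); X2 <- orthoCentered(n, p)
  y1 <- drop(X1 %*% c(0.8, 0, -0.6)) + rnorm(n, sd = 0.5); y1 <- y1 - mean(y1)
  y2 <- drop(X2 %*% c(0.7, 0, 0)) + rnorm(n, sd = 0.5); y2 <- y2 - mean(y2)
  d1 <- gwasDataset(X1, y1); d2 <- gwasDataset(X2, y2)
  params <- list(alpha = c(0.4, 0.2, 0.25, 0.15),
                 sigma2beta = c(0.5, 0.8), sigma2e = c(0.6, 0.9))
  state <- pleiogwas:::.initQuantState(p, 2L, params$sigma2beta[1])
  for (it in 1:200) {
    es <- pleiogwas:::.eStepQuantJoint(state, params, d1, d2)
    state <- list(mu = es$mu, s2 = es$s2, gpost = es$gpost)
  }
  ex <- enumJointQuant(y1, X1, y2, X2, params)
  expect_equal(state$gpost, ex$gpost, tolerance = 1e-6)
  # at the exact-posterior fixed point the bound is tight
  elbo <- elboQuantOf(state, params, d1, d2)
  expect_lte(elbo, ex$logMarg + 1e-8)
  expect_equal(elbo, ex$logMarg, tolerance = 1e-8)
})

test_that("the single-trait fit matches 2^p enumeration on an orthogonal design", {
  set.seed(43)
  n <- 14; p <- 3
  X <- orthoCentered(n, p)
  y <- drop(X %*% c(1, 0, 0)) + rnorm(n, sd = 0.6); y <- y - mean(y)
  d <- gwasDataset(X, y)
  params <- list(alpha = c(0.8, 0.2), sigma2beta = 0.7, sigma2e = 0.5)
  state <- pleiogwas:::.initQuantState(p, 1L, params$sigma2beta)
  for (it in 1:200) {
    es <- pleiogwas:::.eStepQuantSingle(state, params, d)
    state <- list(mu = es$mu, s2 = es$s2, gpost = es$gpost)
  }
  ex <- enumSingleQuant(y, X, 0.2, params$sigma2e, params$sigma2beta)
  expect_equal(state$gpost[, 2], ex$pip, tolerance = 1e-6)
})

test_that("one E-step sweep does not decrease the lower bound", {
  for (seed in 1:5) {
    sim <- smallQuantPair(seed)
    d1 <- sim$train[[1]]; d2 <- sim$train[[2]]
    params <- pleiogwas:::.initQuantParams(list(d1, d2))
    state <- pleiogwas:::.initQuantState(50, 2L, 1)
    before <- elboQuantOf(state, params, d1, d2)
    es <- pleiogwas:::.eStepQuantJoint(state, params, d1, d2)
    state2 <- list(mu = es$mu, s2 = es$s2, gpost = es$gpost)
    after <- elboQuantOf(state2, params, d1, d2)
    expect_gte(after, before - 1e-8 * abs(before))
  }
})

test_that("M-step updates zero the numeric ELBO gradient", {
  sim <- smallQuantPair(77, n = 100, p = 40)
  d1 <- sim$train[[1]]; d2 <- sim$train[[2]]
  opts <- fitOptions()
  params <- pleiogwas:::.initQuantParams(list(d1, d2))
  state <- pleiogwas:::.initQuantState(40, 2L, 1)
  xtxList <- list(colSums(genotypes(d1)^2), colSums(genotypes(d2)^2))
  nVec <- c(100, 100)
  for (it in 1:3) {
    es <- pleiogwas:::.eStepQuantJoint(state, params, d1, d2, xtxList)
    state <- list(mu = es$mu, s2 = es$s2, gpost = es$gpost)
    rss <- vapply(es$residuals, function(r) sum(r^2), numeric(1))
    params <- pleiogwas:::.mStepQuantCore(state, params, rss, xtxList,
                                          nVec, opts)
  }
  rss <- vapply(pleiogwas:::.quantResiduals(state, list(d1, d2)),
                function(r) sum(r^2), numeric(1))
  elboAt <- function(pp) pleiogwas:::.elboQuantCore(state, pp, rss, xtxList,
                                                    nVec)
  h <- 1e-5
  for (k in 1:2) {
    for (slot in c("sigma2e", "sigma2beta")) {
      up <- params; up[[slot]][k] <- up[[slot]][k] * exp(h)
      dn <- params; dn[[slot]][k] <- dn[[slot]][k] * exp(-h)
      grad <- (elboAt(up) - elboAt(dn)) / (2 * h) # d ELBO / d log theta
      expect_lt(abs(grad), 1e-4)
    }
  }
  # softmax-parameterized alpha gradient: sum_j gpost_lj - p * alpha_l = 0
  expect_equal(colSums(state$gpost) - 40 * params$alpha, rep(0, 4),
               tolerance = 1e-8)
  # identical group-posterior rows average to themselves
  st2 <- state; st2$gpost <- matrix(rep(c(0.5, 0.2, 0.2, 0.1), each = 40),
                                    40, 4)
  p2 <- pleiogwas:::.mStepQuantCore(st2, params, rss, xtxList, nVec, opts)
  expect_equal(p2$alpha, c(0.5, 0.2, 0.2, 0.1), tolerance = 1e-10)
})

test_that("full fits are monotone, detect signal, and go quiet on null data", {
  sim <- smallQuantPair(5, n = 150, p = 120, alpha1 = 0.05)
  fit <- fitPleioQuant(sim$train[[1]], sim$train[[2]])
  expectMonotone(elboTrace(fit))
  expect_true(fit@converged)
  expect_gt(prioritizationAuc(1 - lfdr(fit, 1), sim$truth$gamma[, 1]), 0.8)

  # permuted phenotypes: essentially no non-null mass, no selections
  set.seed(8)
  dNull1 <- gwasDataset(genotypes(sim$train[[1]]),
                        sample(phenotype(sim$train[[1]])))
  dNull2 <- gwasDataset(genotypes(sim$train[[2]]),
                        sample(phenotype(sim$train[[2]])))
  fit0 <- fitPleioQuant(dNull1, dNull2)
  expect_lt(sum(fit0@alpha[2:4]), 0.02)
  expect_length(selectGlobalFdr(lfdr(fit0, 1), 0.2)$selected, 0)
  expect_gt(min(lfdr(fit0, 1)), 0.5)
})

test_that("the joint ELBO at an independence-constrained state is the sum of single-trait ELBOs", {
  sim <- smallQuantPair(13, n = 120, p = 60, alpha1 = 0.05, g = 0)
  f1 <- fitSingleQuant(sim$train[[1]])
  f2 <- fitSingleQuant(sim$train[[2]])
  # assemble the product state: gpost_j = outer(gamma1_j, gamma2_j)
  p <- 60
  g1 <- f1@groupPost; g2 <- f2@groupPost
  gJoint <- cbind(g1[, 1] * g2[, 1], g1[, 1] * g2[, 2],
                  g1[, 2] * g2[, 1], g1[, 2] * g2[, 2])
  state <- list(mu = cbind(f1@mu[, 1], f2@mu[, 1]),
                s2 = cbind(f1@s2[, 1], f2@s2[, 1]),
                gpost = gJoint)
  params <- list(alpha = independenceProjection(f1@alpha[2], f2@alpha[2]),
                 sigma2beta = c(f1@sigma2beta, f2@sigma2beta),
                 sigma2e = c(f1@sigma2e, f2@sigma2e))
  elboJoint <- elboQuantOf(state, params, sim$train[[1]], sim$train[[2]])
  expect_equal(elboJoint, lastElbo(f1) + lastElbo(f2), tolerance = 1e-6)
})

test_that("fits require matching SNP sets and quantitative datasets", {
  sim <- smallQuantPair(2, n = 40, p = 20)
  dShort <- gwasDataset(genotypes(sim$train[[2]])[, 1:10],
                        phenotype(sim$train[[2]]))
  expect_error(fitPleioQuant(sim$train[[1]], dShort), "same number of SNPs")
  db <- gwasDataset(matrix(sample(0:2, 200, TRUE), 20, 10),
                    rep(c(0, 1), 10), "binary")
  expect_error(fitPleioQuant(sim$train[[1]], db), "quantitative")
})
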