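test_that("the quadratic bound has fixed curvature 1/4 and touches the log-sigmoid at psi", {
  bt <- pleiogwas:::.bohningTerms(0)
  expect_identical(bt$a, 0.25)
  expect_equal(bt$b, -0.5)
  expect_equal(bt$c, log(2))

  # 121-point grid: exp(-a t^2 / 2 + (1 + b) t - c) <= sigmoid(t),
  # equality at t = psi
  grid <- seq(-6, 6, length.out = 11)
  for (psi in grid) {
    bt <- pleiogwas:::.bohningTerms(psi)
    expect_identical(bt$a, 0.25)
    lower <- exp(-0.5 * bt$a * grid^2 + (1 + bt$b) * grid - bt$c)
    expect_true(all(lower <= plogis(grid) + 1e-12))
    at <- exp(-0.5 * bt$a * psi^2 + (1 + bt$b) * psi - bt$c)
    expect_equal(at, plogis(psi), tolerance = 1e-12)
  }
})

test_that("psi moves to the expected margin and each update block raises the bound", {
  # deterministic q: psi equals the (signed) linear predictor exactly
  eta <- c(1.3, -0.4, 2.2)
  y <- c(1, -1, 1)
  expect_equal(pleiogwas:::.updatePsi(y, eta), y * eta)

  sim <- smallBinaryPair(31, n = 100, p = 40)
  ds <- sim$train
  xtxList <- lapply(ds, function(d) colSums(genotypes(d)^2))
  params <- pleiogwas:::.initBinaryParams(ds)
  state <- pleiogwas:::.initQuantState(40, 2L, 1)
  opts <- fitOptions()
  elbo <- pleiogwas:::.elboBinaryCore(state, params, ds, xtxList)
  for (it in 1:4) {
    es <- pleiogwas:::.eStepBinary(state, params, ds, xtxList)
    state <- es$state
    params <- pleiogwas:::.mStepBinaryCore(state, es$params, opts)
    elboNew <- pleiogwas:::.elboBinaryCore(state, params, ds, xtxList)
    expect_gte(elboNew, elbo - 1e-8 * abs(elbo))
    elbo <- elboNew
  }
})

test_that("the sweep on Bohning pseudo-data maximizes the bound coordinate-wise", {
  sim <- smallBinaryPair(32, n = 60, p = 4, alpha1 = 0.3)
  ds <- sim$train
  xtxList <- lapply(ds, function(d) colSums(genotypes(d)^2))
  params <- pleiogwas:::.initBinaryParams(ds)
  state <- pleiogwas:::.initQuantState(4, 2L, 1)
  # several passes so the state settles near a coordinate-wise optimum,
  # then freeze (psi, phi) and iterate the sweep alone to convergence
  for (it in 1:5) {
    es <- pleiogwas:::.eStepBinary(state, params, ds, xtxList)
    state <- es$state
    params <- es$params
  }
  frozen <- params
  for (it in 1:50) {
    a <- pleiogwas:::.BOHNING_A
    mom <- pleiogwas:::.effMoments(state)
    pseudo <- lapply(1:2, function(k) {
      d <- ds[[k]]
      bt <- pleiogwas:::.bohningTerms(frozen$psi[[k]])
      d@phenotype * (1 + bt$b) / a -
        drop(d@covariates %*% frozen$phi[[k]]) -
        drop(d@genotypes %*% mom$mean[, k])
    })
    sw <- pleiogwas:::.sweepJoint(ds[[1]]@genotypes, ds[[2]]@genotypes,
                                  xtxList[[1]], xtxList[[2]],
                                  pseudo[[1]], pseudo[[2]],
                                  state$mu, state$s2, state$gpost,
                                  log(frozen$alpha), c(4, 4),
                                  frozen$sigma2beta)
    state <- list(mu = sw$mu, s2 = sw$s2, gpost = sw$gpost)
  }
  # numeric check: perturbing any single slab coordinate cannot improve the
  # bound, and the numeric optimum of (mu_j1, s2_j1) matches the update
  base <- pleiogwas:::.elboBinaryCore(state, frozen, ds, xtxList)
  for (j in 1:4) {
    f <- function(par) {
      st <- state
      st$mu[j, 1] <- par[1]
      st$s2[j, 1] <- exp(par[2])
      -pleiogwas:::.elboBinaryCore(st, frozen, ds, xtxList)
    }
    opt <- optim(c(state$mu[j, 1], log(state$s2[j, 1])), f,
                  method = "BFGS",
                  control = list(reltol = 1e-14, maxit = 500))
    expect_equal(opt$par[1], state$mu[j, 1], tolerance = 1e-5)
    expect_equal(exp(opt$par[2]), state$s2[j, 1], tolerance = 1e-5)
    expect_lte(-opt$value, base + 1e-6)
  }
})

test_that("covariate updates solve the weighted least-squares problem", {
  # balanced null data with intercept only: phi stays at ~0
  set.seed(40)
  G <- matrix(sample(0:2, 400, TRUE, prob = c(.4, .4, .2)), 40, 10)
  y <- rep(c(0, 1), 20)
  d <- gwasDataset(G, y, "binary")
  fit <- fitSingleBinary(d)
  expect_lt(abs(fit@phi[[1]][1]), 0.15)
  expect_gt(min(lfdr(fit, 1)), 0.8)
  expect_length(selectGlobalFdr(lfdr(fit, 1), 0.2)$selected, 0)

  # numeric maximization of the bound in phi agrees with the WLS solve
  # (at a fixed variational state and fixed psi)
  set.seed(41)
  Z <- cbind(1, rnorm(40))
  d2 <- gwasDataset(G, y, "binary", covariates = Z)
  ds <- list(d2)
  xtxList <- list(colSums(genotypes(d2)^2))
  params <- pleiogwas:::.initBinaryParams(ds)
  state <- pleiogwas:::.initQuantState(10, 1L, 1)
  state$mu[] <- rnorm(10, 0, 0.2) # nonzero SNP contributions
  params$psi[[1]] <- rnorm(40, 0, 0.5)
  mom <- pleiogwas:::.effMoments(state)
  Xm <- drop(genotypes(d2) %*% mom$mean[, 1])
  bt <- pleiogwas:::.bohningTerms(params$psi[[1]])
  w <- phenotype(d2) * (1 + bt$b) / bt$a
  params$phi[[1]] <- pleiogwas:::.updateCovariates(covariates(d2), w, Xm)
  f <- function(phi) {
    pp <- params; pp$phi[[1]] <- phi
    -pleiogwas:::.elboBinaryCore(state, pp, ds, xtxList)
  }
  opt <- optim(params$phi[[1]], f, method = "BFGS",
                control = list(reltol = 1e-14, maxit = 500))
  expect_equal(opt$par, unname(params$phi[[1]]), tolerance = 1e-6)

  # duplicated covariate column is rank-deficient
  d3 <- gwasDataset(G, y, "binary", covariates = cbind(Z, Z[, 2]))
  expect_error(fitSingleBinary(d3), "rank-deficient")
})

test_that("the double bound never exceeds the exact log marginal (quadrature oracle)", {
  set.seed(50)
  n <- 10
  x1 <- sample(0:2, n, TRUE); x2 <- sample(0:2, n, TRUE)
  y1 <- c(rep(1, 5), rep(0, 5)); y2 <- rep(c(1, 0), 5)
  d1 <- gwasDataset(matrix(x1), y1, "binary")
  d2 <- gwasDataset(matrix(x2), y2, "binary")
  fit <- fitPleioBinary(d1, d2)
  exact <- enumBinaryLogMarg(d1, d2, fit@alpha, fit@sigma2beta, fit@phi)
  expect_lte(lastElbo(fit), exact + 1e-8)
})

test_that("relabeling cases and controls mirrors the fit", {
  sim <- smallBinaryPair(60, n = 80, p = 30)
  d <- sim$train[[1]]
  dFlip <- gwasDataset(genotypes(d), -phenotype(d), "binary")
  f <- fitSingleBinary(d)
  fFlip <- fitSingleBinary(dFlip)
  expect_equal(lastElbo(f), lastElbo(fFlip), tolerance = 1e-6)
  expect_equal(posteriorEffect(f, 1), -posteriorEffect(fFlip, 1),
               tolerance = 1e-6)
})

test_that("binary fits are monotone and reject degenerate phenotypes", {
  sim <- smallBinaryPair(61, n = 100, p = 60)
  fit <- fitPleioBinary(sim$train[[1]], sim$train[[2]])
  expectMonotone(elboTrace(fit))
  expect_true(fit@converged)
  expect_error(gwasDataset(matrix(sample(0:2, 30, TRUE), 10, 3),
                           rep(1, 10), "binary"),
               "single distinct value")
})
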