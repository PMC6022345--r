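# Benchmarking metrics: rank-based AUC for SNP prioritization, power and
# realized FDR of a selection, LD-aware discovery accounting, and a
# replicate-level simulation benchmark harness.

#' Rank-based AUC of SNP prioritization scores
#'
#' Mann-Whitney AUC of non-null versus null SNPs with midrank ties: the
#' probability that a randomly chosen non-null SNP outscores a randomly
#' chosen null one.
#'
#' @param scores numeric ranking scores (higher = more likely non-null),
#'   e.g. `1 - lfdr`.
#' @param truth binary vector: 1 for non-null SNPs.
#' @return scalar AUC in [0, 1].
#' @export
prioritizationAuc <- function(scores, truth) {
  truth <- as.integer(truth != 0)
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both null and non-null SNPs are required")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Power and realized FDR of a selection
#'
#' @param selected integer indices of selected SNPs.
#' @param truth binary vector: 1 for non-null SNPs.
#' @return named vector `c(power, fdr)`: true positives over the number of
#'   non-nulls, and false positives over `max(1, |selection|)`.
#' @export
powerAndFdr <- function(selected, truth) {
  truth <- as.integer(truth != 0)
  nPos <- sum(truth)
  if (nPos == 0L) stop("no non-null SNPs in the truth vector")
  tp <- sum(truth[selected])
  c(power = tp / nPos,
    fdr = (length(selected) - tp) / max(1L, length(selected)))
}

#' LD-aware discovery accounting
#'
#' A causal SNP counts as discovered when it, or any SNP whose absolute
#' genotype correlation with it exceeds `rThreshold`, is selected; the
#' true-null set excludes the causal SNPs and all their high-LD proxies.
#' This credits discoveries that tag a causal variant through linkage
#' disequilibrium rather than hitting it exactly.
#'
#' @param selected integer indices of selected SNPs.
#' @param causalSet integer indices of the causal SNPs.
#' @param genotypes genotype matrix used to compute correlations (ignored
#'   when `corMat` is given).
#' @param corMat optional precomputed p x p correlation matrix.
#' @param rThreshold high-LD correlation threshold in (0, 1).
#' @return list with `discovered` (logical per causal SNP), `nDiscovered`,
#'   `trueNulls` (indices outside the causal SNPs and their proxies), and
#'   `falsePositives` (selected true nulls).
#' @export
ldAwareDiscovery <- function(selected, causalSet, genotypes = NULL,
                             corMat = NULL, rThreshold = 0.8) {
  stopifnot(rThreshold > 0, rThreshold < 1)
  if (is.null(corMat)) {
    stopifnot(!is.null(genotypes))
    corMat <- abs(cor(genotypes))
  } else {
    corMat <- abs(corMat)
  }
  p <- ncol(corMat)
  discovered <- vapply(causalSet, function(j) {
    j %in% selected || any(corMat[selected, j] > rThreshold)
  }, logical(1))
  proxies <- unique(unlist(lapply(causalSet, function(j) {
    which(corMat[, j] > rThreshold)
  })))
  trueNulls <- setdiff(seq_len(p), union(causalSet, proxies))
  list(discovered = discovered, nDiscovered = sum(discovered),
       trueNulls = trueNulls,
       falsePositives = intersect(selected, trueNulls))
}

.benchmarkOne <- function(cellCfg, methods, tau, computeLrt) {
  sim <- if (cellCfg$traitKind == "binary") simulateBinaryPair(cellCfg)
         else simulateQuantPair(cellCfg)
  quant <- cellCfg$traitKind == "quantitative"
  fits <- list()
  if ("pleio" %in% methods || computeLrt) {
    fits$joint <- if (quant) {
      fitPleioQuant(sim$train[[1L]], sim$train[[2L]])
    } else fitPleioBinary(sim$train[[1L]], sim$train[[2L]])
  }
  if ("single" %in% methods || computeLrt) {
    fits$single <- lapply(sim$train, function(d) {
      if (quant) fitSingleQuant(d) else fitSingleBinary(d)
    })
  }
  rows <- list()
  scoreFit <- function(fitFor, method) {
    for (k in 1:2) {
      f <- fitFor(k)
      lf <- lfdr(f, if (f@model == "joint") k else 1L)
      sel <- selectGlobalFdr(lf, tau)$selected
      pf <- powerAndFdr(sel, sim$truth$gamma[, k])
      pred <- predict(f, sim$test[[k]]$genotypes,
                      trait = if (f@model == "joint") k else 1L)
      predScore <- if (quant) {
        cor(pred, sim$test[[k]]$phenotype)
      } else {
        prioritizationAuc(pred, sim$test[[k]]$phenotype == 1)
      }
      rows[[length(rows) + 1L]] <<- data.frame(
        method = method, trait = k,
        auc = prioritizationAuc(1 - lf, sim$truth$gamma[, k]),
        power = pf["power"], fdr = pf["fdr"], prediction = predScore)
    }
  }
  if ("pleio" %in% methods) scoreFit(function(k) fits$joint, "pleio")
  if ("single" %in% methods) scoreFit(function(k) fits$single[[k]], "single")
  if ("lasso" %in% methods) {
    if (!requireNamespace("glmnet", quietly = TRUE))
      stop("the lasso baseline requires the glmnet package")
    for (k in 1:2) {
      d <- sim$train[[k]]
      fam <- if (quant) "gaussian" else "binomial"
      yk <- if (quant) d@phenotype else as.integer(d@phenotype == 1)
      cv <- glmnet::cv.glmnet(d@genotypes, yk, family = fam, nfolds = 5)
      co <- as.numeric(coef(cv, s = "lambda.min"))[-1L]
      predRaw <- drop(sweep(sim$test[[k]]$genotypes, 2L, d@colMeans) %*% co)
      predScore <- if (quant) {
        if (sd(predRaw) == 0) 0 else {
          cor(predRaw + d@phenoMean, sim$test[[k]]$phenotype)
        }
      } else prioritizationAuc(predRaw, sim$test[[k]]$phenotype == 1)
      rows[[length(rows) + 1L]] <- data.frame(
        method = "lasso", trait = k,
        auc = prioritizationAuc(abs(co), sim$truth$gamma[, k]),
        power = NA_real_, fdr = NA_real_, prediction = predScore)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (computeLrt) {
    lrt <- pleiotropyTest(fits = list(joint = fits$joint,
                                      single1 = fits$single[[1L]],
                                      single2 = fits$single[[2L]]))
    out$lrtReject <- lrt@pValue < 0.05
  }
  out
}

#' Replicate-level simulation benchmark
#'
#' For every row of `grid` and every replicate: simulate a cohort pair,
#' fit the requested methods, select SNPs per trait at global FDR bound
#' `tau`, and score prioritization AUC, power, realized FDR, and held-out
#' prediction (Pearson correlation for quantitative traits, AUC for binary
#' traits). The lasso baseline (glmnet, 5-fold cross-validated) is scored
#' on AUC and prediction only — its FDR is not controllable, so power is
#' not reported for it. Replicate seeds derive deterministically from
#' `seed`, so reports are reproducible.
#'
#' @param grid data.frame of scenario axes; recognized columns: `g`, `rho`,
#'   `h2`, `traitKind`, `alpha1`, `n`, `p` (missing columns fall back to
#'   `baseConfig`).
#' @param methods subset of `c("pleio", "single", "lasso")`.
#' @param nReplicates replicates per grid row.
#' @param seed master seed.
#' @param tau global FDR bound for selections.
#' @param baseConfig a [simConfig()] providing defaults for axes the grid
#'   omits.
#' @param computeLrt also run the pleiotropy test per replicate and report
#'   the rejection rate at level 0.05.
#' @return list with `replicates` (one row per replicate x method x trait)
#'   and `summary` (means and standard errors per grid cell x method x
#'   trait).
#' @export
runBenchmark <- function(grid, methods = c("pleio", "single"),
                         nReplicates = 10L, seed = 1L, tau = 0.2,
                         baseConfig = simConfig(), computeLrt = FALSE) {
  bad <- setdiff(methods, c("pleio", "single", "lasso"))
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  repSeeds <- .subSeeds(seed, nrow(grid) * nReplicates)
  reps <- list()
  for (cell in seq_len(nrow(grid))) {
    cfg <- baseConfig
    for (col in intersect(names(grid),
                          c("g", "rho", "h2", "traitKind", "alpha1"))) {
      cfg[[col]] <- if (is.factor(grid[[col]][cell]))
        as.character(grid[[col]][cell]) else grid[[col]][cell]
    }
    if ("n" %in% names(grid)) cfg$n1 <- cfg$n2 <- as.integer(grid$n[cell])
    if ("p" %in% names(grid)) cfg$p <- as.integer(grid$p[cell])
    for (r in seq_len(nReplicates)) {
      cfg$seed <- repSeeds[(cell - 1L) * nReplicates + r]
      res <- .benchmarkOne(cfg, methods, tau, computeLrt)
      res$cell <- cell
      res$replicate <- r
      for (col in names(grid)) res[[col]] <- grid[[col]][cell]
      reps[[length(reps) + 1L]] <- res
    }
  }
  reps <- do.call(rbind, reps)
  metrics <- intersect(c("auc", "power", "fdr", "prediction", "lrtReject"),
                       names(reps))
  agg <- aggregate(reps[metrics],
                   by = reps[c("cell", "method", "trait")],
                   FUN = function(x) mean(x, na.rm = TRUE))
  se <- aggregate(reps[metrics],
                  by = reps[c("cell", "method", "trait")],
                  FUN = function(x) {
                    x <- x[!is.na(x)]
                    if (length(x) < 2L) NA_real_ else sd(x) / sqrt(length(x))
                  })
  names(se)[match(metrics, names(se))] <- paste0(metrics, "SE")
  summary <- merge(agg, se, by = c("cell", "method", "trait"))
  summary <- merge(summary, cbind(cell = seq_len(nrow(grid)), grid),
                   by = "cell")
  list(replicates = reps, summary = summary)
}
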