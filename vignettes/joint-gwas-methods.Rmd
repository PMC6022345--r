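---
title: "Leveraging pleiotropy across two GWAS cohorts: model, algorithm, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leveraging pleiotropy across two GWAS cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiogwas)
```

## The problem

Complex traits are polygenic: many variants with small effects, each hard to
detect at realistic sample sizes. When two traits share risk variants
(pleiotropy), a joint analysis can borrow strength across them — but most
joint methods require both phenotypes measured on the *same* individuals.
`pleiogwas` targets the complementary design: two GWAS collected on
*different* cohorts, sharing only their SNP panel.

## The model

For cohort $k \in \{1,2\}$ with centered phenotype $y_k$ and centered
genotypes $X_k$ over the same $p$ SNPs,

$$ y_k \mid X_k \sim \mathcal{N}\!\Big(\sum_{j=1}^p \gamma_{kj}\beta_{kj}
   x_{kj},\ \sigma^2_{e_k} I\Big), \qquad
   \beta_{kj} \sim \mathcal{N}(0, \sigma^2_{\beta_k}), $$

a spike-and-slab ("binary mask") prior in which $\gamma_{kj} \in \{0,1\}$
gates SNP $j$'s effect on trait $k$. Pleiotropy enters through the joint law
of the per-SNP indicator pair: $[\gamma_{1j}, \gamma_{2j}]$ is multinomial
over the four groups $L = \{00, 01, 10, 11\}$ with probabilities
$\alpha = (\alpha_{00}, \alpha_{01}, \alpha_{10}, \alpha_{11})$. The group
order is fixed package-wide as written. Dependence between
$\gamma_{1j}$ and $\gamma_{2j}$ — i.e.
$\alpha_{11} \neq \alpha_{1*}\alpha_{*1}$ with marginals
$\alpha_{1*} = \alpha_{10}+\alpha_{11}$, $\alpha_{*1} =
\alpha_{01}+\alpha_{11}$ — is exactly what lets one cohort's evidence
reweight the other's.

For case-control cohorts the Gaussian likelihood is replaced by a logistic
one: with disease status coded $y_{ki} \in \{-1, +1\}$ and linear predictor
$\eta_{ki} = z_{ki}^\top \phi_k + \sum_j \gamma_{kj}\beta_{kj}x_{kij}$
(fixed-effect covariates $Z_k$ with a leading intercept),
$\Pr(y_{ki}) = \sigma(y_{ki}\eta_{ki})$.

## Variational EM

The marginal likelihood sums over $4^p$ indicator configurations, so the
posterior is approximated by a fully factorized (mean-field) family: one
factor per SNP carrying a four-group posterior $\alpha_{lj}$ and per-trait
slab moments $\mu_{kj}, s^2_{kj}$. Coordinate ascent on the evidence lower
bound (ELBO) gives closed-form sweeps:

* slab: $s^2_{kj} = \sigma^2_{e_k}/(x^\top x + \sigma^2_{e_k}/\sigma^2_{\beta_k})$,
  $\mu_{kj} = x^\top r_{kj} / (x^\top x + \sigma^2_{e_k}/\sigma^2_{\beta_k})$,
  with $r_{kj}$ the expected residual excluding SNP $j$ (maintained
  incrementally, so a sweep is $O(np)$);
* group posterior: $\alpha_{lj} \propto \alpha_l
  \exp(u_{1j}\mathbb{1}[l \in \{10,11\}] + u_{2j}\mathbb{1}[l \in \{01,11\}])$,
  where $u_{kj} = \tfrac12\log(s^2_{kj}/\sigma^2_{\beta_k}) +
  \mu^2_{kj}/(2 s^2_{kj})$ is the per-trait log evidence gain;
* M-step: $\hat\alpha_l = \frac1p\sum_j \alpha_{lj}$;
  $\hat\sigma^2_{\beta_k}$ the inclusion-weighted second moment of the slabs;
  $\hat\sigma^2_{e_k}$ the expected residual sum of squares over $n_k$.
  Because the spike component of each factor coincides with the prior, spike
  terms cancel from the bound and all three updates are exact stationary
  points (the test suite checks this by finite differences).

The sweeps are implemented in C++ (RcppArmadillo); everything else is
vectorized R. The ELBO is monotone across every E- and M-step — this is the
suite's central correctness oracle, along with exact-enumeration checks: for
orthogonal genotype columns the mean-field family contains the true
posterior, and the fitted factors must match brute-force enumeration over
all $4^p$ configurations to $10^{-6}$ (they match to machine precision).

For binary traits the log-sigmoid is bounded below by a fixed-curvature
quadratic, tight at a per-observation location $\psi_{ki}$
($a = \tfrac14$; $b, c$ the standard coefficient functions of $\psi$).
Because the curvature is constant, the E-step reduces *exactly* to the
quantitative sweep on pseudo-data with residual precision $a$ and working
response $y(1+b)/a$ minus the covariate offset — one shared kernel serves
both models. Each outer iteration updates $\psi$ (to the expected margin
$y_i\,\mathbb{E}[\eta_i]$, the stationary point of the expected surrogate),
then the covariate coefficients $\phi_k$ by weighted least squares, then the
per-SNP factors, then $(\alpha, \sigma^2_\beta)$; the resulting double
(quadratic + Jensen) bound is monotone and never exceeds the true log
marginal (checked against numeric quadrature).

## Inference

**lfdr and selection.** The local false discovery rate of SNP $j$ for trait
$k$ is $1 - \sum_{l \in L_k}\alpha_{lj}$ with $L_1 = \{10,11\}$,
$L_2 = \{01,11\}$. `selectGlobalFdr()` implements direct posterior
probability control: raise the lfdr threshold $\zeta$ from 0 and keep the
largest value at which the mean lfdr of the selected set stays at or below
the target $\tau$. Ties at $\zeta$ are all included; the implementation
scans the unique lfdr values, so the estimated FDR of the reported set never
exceeds $\tau$ even with ties.

**Prediction.** The posterior-mean effect $\mathbb{E}(\gamma_{kj}\beta_{kj})
= (\sum_{l\in L_k}\alpha_{lj})\,\mu_{kj}$ is applied to raw genotypes using
the training centering constants $c_{k0}, c_{kj}$ stored in the fit; binary
predictions pass the linear predictor (including $z^\top\phi$) through the
inverse logit. Evaluation uses Pearson correlation (quantitative) and
midrank Mann-Whitney AUC (binary).

**Pleiotropy test.** $H_0: \alpha_{11} = \alpha_{1*}\alpha_{*1}$ against the
free four-group alternative. Under the product constraint the joint model
factorizes exactly into two single-trait two-group models, so the null fit
is the pair of single-trait fits and
$\lambda = 2(\mathcal{L}_{\text{joint}} - \mathcal{L}_1 - \mathcal{L}_2)$,
referred to $\chi^2_1$, with the converged lower bounds standing in for the
intractable log marginals. Since both sides are surrogates, $\lambda$ can
come out marginally negative; it is clamped at zero and the event recorded
in the result. Because $\lambda$ is a small difference of bounds of
magnitude $\sim 10^3$–$10^4$, `pleiotropyTest()` runs its fits at a relative
tolerance of $10^{-8}$ (an ordinary fit uses $10^{-5}$, which would leave
optimization error of the same order as $\lambda$).

## The simulation engine

The generator reproduces the reference experimental design and is the basis
of the acceptance checks:

* **Genotypes.** Latent standard-Gaussian AR($\rho$) rows (default
  $\rho = 0.5$) discretized at the Hardy-Weinberg quantiles of a per-SNP
  MAF drawn uniformly from $[0.05, 0.5]$; the MAF vector is shared between
  the two cohorts (they genotype the same SNPs), while the draws are
  independent (different individuals).
* **Statuses.** Trait 1 gets exactly $\mathrm{round}(p\alpha_1)$ non-null
  SNPs; trait 2 the same count, with
  $\mathrm{round}(p\alpha_1(\alpha_1 + g(1-\alpha_1)))$ of them drawn from
  trait 1's non-null set — interpolating from independence ($g=0$) to full
  sharing ($g=1$). Counts round half *up* (the $g=0$ default design yields
  an expected overlap of exactly 0.5, which rounds to 1). An explicit
  four-group $\alpha$ override supports asymmetric designs.
* **Effects and noise.** Effects are standard normal by default
  (`truncated-normal`, truncation at $\pm 2$, and Student $t_4$ options
  cover the heavy-tailed robustness scenarios; the truncation bound and
  degrees of freedom are package choices, as only the distribution families
  are prescribed). The noise variance is set against the *realized* signal
  variance so the plug-in heritability equals the target exactly per
  replicate, defaulting to $h^2 = 0.5$.
* **Case-control sampling.** Liability $= X(\zeta\circ\gamma) + e$ with
  noise targeting liability-scale $h^2$; the case threshold is the
  $(1-\text{prevalence})$ quantile of one auxiliary population draw
  ($10\times$ the cohort size, capped at 50,000 — a closed form is
  unavailable because the discretized genotype signal has no simple law);
  the population is then oversampled (budget-capped) and retained at the
  requested case:control ratio, 1:1 by default at prevalence 0.1. Test
  cohorts are drawn by the same case-control scheme as training (the
  alternative, population sampling, is equally defensible; this choice keeps
  train and test exchangeable).
* **Reproducibility.** Each logical component (genotypes, statuses,
  effects, noise/sampling) draws from its own sub-stream of the master
  seed, so changing $g$ re-labels SNPs without perturbing genotypes. For
  binary cohorts the genotype and noise draws are necessarily interleaved
  by rejection sampling, so that guarantee applies at fixed $g$.

What the simulator does *not* emulate: realistic block-structured LD (AR
correlation decays geometrically), allele-frequency/effect-size coupling,
population stratification, or genotyping error. Passing tests therefore
demonstrate correctness of the method under its own generative assumptions
plus moderate autoregressive LD, not performance on any particular real
cohort; the PLINK reader exists precisely so real genotypes can replace the
generator.

## Defaults and numerical choices

| Parameter | Default | Notes |
|---|---|---|
| `tol` | $10^{-5}$ relative ELBO change | $10^{-8}$ inside the LRT |
| `maxIter` | 1000 | typical fits converge in 10–40 sweeps |
| variance floors | $10^{-10}$ | prevents slab/noise collapse |
| $\alpha$ floor | $10^{-12}$ | before logarithms |
| init | $\mu=0$, $s^2=\sigma^2_\beta=1$, uniform group posteriors, $\sigma^2_e = \mathrm{Var}(y)/2$, $\alpha = (0.99, 0.0033, 0.0033, 0.0034)$ | weakly informative, sparse prior mass |
| $\psi$ init | 0; $\phi$ init | intercept-only logistic closed form |
| sweep order | fixed $1..p$ | residuals updated incrementally |
| $\tau$ | 0.2 | conventional global FDR bound for GWAS prioritization |

Degenerate inputs: constant genotype columns are retained with a warning
(they carry no evidence and recover the prior); missing dosages are
mean-imputed per SNP before centering; a phenotype with a single distinct
value is an error; rank-deficient covariate matrices are an error naming
the offending columns.

## Benchmark scales

The replicate-level studies in the test suite and the acceptance script run
at a reduced desk scale — $p = 2000$, $n = 600$ per cohort, 24 replicate
pairs across $g \in \{0, 0.5, 1\}$ for the FDR studies, 200 replicates for
the type-I-error study of the test, and $n = 3000$ for heritability
recovery — chosen to keep the full structure of the reference design
(identical $\rho$, $h^2$, $\alpha_1$, prevalence) at a few minutes of
runtime. `runBenchmark()` exposes the full-scale configuration
($p = 20{,}000$, $n = 3000$, 50 replicates) through its `grid` and
`baseConfig` arguments.

## Known limitations

* **Two traits only.** The four-group construction scales as $2^K$ groups
  in the number of traits; no $K > 2$ support.
* **Mean-field under LD.** With correlated SNPs the factorized posterior
  underestimates joint uncertainty; empirically the ranking behaves well
  under moderate AR correlation, and the LD-aware discovery accounting
  (`ldAwareDiscovery()`) is the right lens for performance when proxies tag
  causal variants.
* **The pleiotropy LRT is conservative in ultra-sparse designs.** At the
  reduced scale with $\alpha_1 = 0.005$ and $g = 0$ the independence value
  of $\alpha_{11}$ is $2.5\times10^{-5}$ — an expected $p\,\alpha_{11} =
  0.05$ shared SNPs — so the $\chi^2_1$ regularity conditions fail near the
  boundary and the realized type-I error falls well below nominal (the
  acceptance suite measures this directly). With denser non-null
  proportions the rejection rate approaches the nominal level, and power
  under full sharing is essentially 1; p-values near the 0.05 boundary in
  very sparse settings should be read as conservative.
* **No quality control.** MAF/missingness/HWE filtering and relatedness
  pruning are left to standard upstream tools; the package consumes
  pre-filtered PLINK filesets.

## A worked example

```{r example}
cfg <- simConfig(n1 = 400, n2 = 400, p = 500, nTest = 100,
                 alpha1 = 0.02, g = 1, h2 = 0.5, seed = 42)
sim <- simulateQuantPair(cfg)
fit <- fitPleioQuant(sim$train[[1]], sim$train[[2]])
fit

sel <- selectGlobalFdr(lfdr(fit, 1), tau = 0.2)
powerAndFdr(sel$selected, sim$truth$gamma[, 1])

cor(predict(fit, sim$test[[1]]$genotypes, trait = 1),
    sim$test[[1]]$phenotype)

pleiotropyTest(sim$train[[1]], sim$train[[2]])
```
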