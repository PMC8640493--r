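---
title: "Methods: rank-based gene-pair signatures for immunotherapy benefit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-based gene-pair signatures for immunotherapy benefit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brgpi)
```

## The problem and the model

Predictive biomarkers for anti-PD-1 immunotherapy built on absolute
expression levels travel poorly between measurement platforms: RNA-seq
counts, TPM and immunohistochemistry scores live on incompatible scales, and
cross-platform normalization is itself a source of bias. Rank-based
gene-pair signatures sidestep the problem by using only *within-sample*
comparisons. For an oriented pair of genes $(a, b)$ and sample $i$, the
feature is the indicator

$$ s_{ab}(i) \;=\; \mathbf{1}\{\,x_{ai} > x_{bi}\,\}, $$

which depends only on whether gene $a$ is expressed above gene $b$ *in that
sample*. Any strictly increasing per-sample transformation of the
measurements — depth scaling, log compression, ordinal re-scoring — leaves
every $s_{ab}$ unchanged, so a signature built from such indicators needs no
normalization at all. Ties score 0; this matters in practice because ordinal
protein scores (IHC) can tie, and the rule must be fixed and documented
(here: "strictly greater scores 1, otherwise 0").

The index is a linear risk score over $K$ selected pairs,

$$ \mathrm{score}(i) \;=\; \sum_{k=1}^{K} \beta_k \, s_k(i), $$

with weights $\beta_k$ taken from a joint multivariate Cox
proportional-hazards fit against progression-free survival (PFS). Patients
are dichotomized at a cutoff $c$ (high risk iff score $> c$; a score exactly
equal to $c$ is low — an arbitrary but fixed boundary convention).

The package ships the frozen published four-pair index for
anti-PD-1-treated NSCLC:

```{r}
published_signature()
```

## The construction pipeline

`brgpi()` reproduces the standard construction:

1. **Pairs.** All $\binom{n}{2}$ oriented pairs of the panel genes present
   in the expression matrix; orientation follows the panel's canonical
   order. Orientation is a pure convention: flipping a pair maps its
   indicator row $s$ to $1-s$ on tie-free data, which negates its Cox
   coefficient without changing which pairs are informative or how samples
   are ranked.
2. **Constancy filter.** Pairs whose indicator mean lies outside
   $[m, 1-m]$ (default $m = 0.2$) are dropped: a near-constant indicator
   carries no survival contrast. The threshold is exposed (`min_frac`)
   because published pair counts in this literature typically reflect an
   unstated prefilter that cannot be reverse-engineered; we make ours
   explicit instead of asserting someone else's count.
3. **Screen.** Each surviving pair is tested by univariate Cox regression
   on PFS; pairs with two-sided Wald $p < \alpha$ (default 0.05,
   deliberately uncorrected, as is conventional for this construction) are
   candidates. A Benjamini–Hochberg option exists behind `adjust = "BH"`
   and is off by default.
4. **Select.** Forward stepwise multivariate Cox over the candidates,
   adding at each step the pair that most decreases the AIC of the joint
   fit, stopping at no improvement or `k_max` pairs (default 4). "Minimum
   criteria" phrasing in this literature is read as minimum-AIC stepwise —
   the most common operationalization; the procedure is deterministic given
   its inputs.
5. **Cutoff.** The classification cutoff maximizes Youden's
   $J = \mathrm{sens} + \mathrm{spec} - 1$ on the time-dependent ROC of the
   training scores at the model horizon (12 months; "one-year PFS").

## Survival machinery and numerical choices

Cox models are fitted by `survival::coxph.fit` (Efron tie correction by
default, Breslow behind a flag for oracle cross-checks), with standard
errors from the observed information and two-sided Wald p-values — the
conventional choice for per-feature screens. Two degenerate regimes are
handled explicitly rather than propagated:

* a covariate with no contrast gets $\beta = 0$, infinite SE, $p = 1$;
* a monotone partial likelihood (perfect separation, which *will* happen
  for binary indicators on small cohorts) is capped at $|\beta| = 15$ and
  flagged non-converged instead of silently diverging.

The log-rank test and Kaplan–Meier curves come from `survival::survdiff` /
`survfit`. The log-rank p-value is asymptotic ($\chi^2_{k-1}$); at very
small group sizes (n around 8) it is visibly anti-conservative relative to
the exact permutation null — the test suite documents this by checking
agreement on a fixture where the approximation is accurate and by
enumeration elsewhere. The per-pair Wald screen is likewise mildly
anti-conservative at a few hundred events (measured pooled type-I rate
about 0.054 at nominal 0.05 in the null simulations below).

**Time-dependent ROC.** The cumulative/dynamic estimator at horizon $\tau$:
cases are subjects with an observed event by $\tau$, controls are subjects
event-free past $\tau$, and subjects censored before $\tau$ are removed
with inverse-probability-of-censoring weights $1/\hat G(T_i^-)$ (cases) and
$1/\hat G(\tau)$ (controls), where $\hat G$ is the Kaplan–Meier estimate of
the censoring distribution. Sensitivity/specificity are evaluated at
midpoints between consecutive unique score values (plus sentinels), so the
Youden cutoff of a perfectly separating score falls strictly between the
two score clusters; the AUC is the trapezoidal integral of the ROC polygon,
which with no censoring equals the exhaustive pair-counting empirical AUC
exactly (ties count 1/2). If all scores are identical the grid is flagged
degenerate and the AUC is 0.5 by convention. The smoothed
nearest-neighbour variant of the estimator is deliberately not implemented;
the IPCW form is the transparent default.

Newton convergence tolerance is `survival`'s default (`eps = 1e-9`, max 100
iterations); stepwise AIC comparisons use a `1e-9` improvement margin so
floating-point ties never cycle; ties in the Youden criterion resolve to
the lowest threshold (first maximum).

## The synthetic-cohort generator

No clinical data ship with the package, so every downstream stage is
validated against simulated cohorts with planted truth
(`sim_config()` / `generate_cohort()`):

* **Expression.** Genes are independent log-normals with gene-specific
  means (`exp(N(mu_g, 1))`, `mu_g ~ N(0, 0.75)`); within each planted pair
  both genes share a mean, putting the planted indicator's prevalence near
  1/2. Gene–gene correlation and count-specific noise (negative binomial,
  library size) are intentionally *not* modelled: the indicators discard
  scale information, and what must be exercised is the ordering structure.
* **Survival.** Exponential event times under exact proportional hazards:
  rate $\lambda_i = \lambda_0 \exp(r_i - \bar r)$ with
  $r_i = \sum_k \beta_k s_k(i)$ (plus an optional PD-L1 term) and $\bar r$
  the config-determined expectation of the linear predictor (prevalence
  1/2 per pair). Centering makes `baseline_hazard` (default 0.08/month,
  i.e. a median PFS of about 8.7 months for the average patient) describe
  the *average* patient rather than the zero-score patient; Cox
  coefficients are invariant to the constant. Defaults plant the published
  four pairs with their published coefficients.
* **Censoring.** Independent uniform on $(0, C]$ — an administrative
  analogue — with $C$ solved numerically so the expected censored fraction
  equals `censor_rate`. Realized fractions land within a few percent of the
  target at cohort sizes in the hundreds.
* **Response.** A latent variable $u_i = r_i + \text{noise}$ (logistic,
  scale `response_noise`) cut at its empirical 5% / 30% / 65% quantiles
  gives CR / PR / SD / PD with progression probability increasing in risk —
  a cumulative-logit-style mechanism chosen only to produce the monotone
  score-versus-response trend, not to assert biology.
* **Covariates.** PD-L1 high with probability `pdl1_high_frac` (0.35),
  independent of the pair score by default (PD-L1 is accepted only as a
  pre-dichotomized label; no TPS threshold is implied), with an optional
  `pdl1_beta` hazard knob for planting a PD-L1 effect; squamous pathology
  with probability 0.4; male sex 0.6. Time unit is months throughout.
* **Platforms.** The returned expression passes through a per-sample
  strictly monotone distortion (`linear`, `log`, `power` or `rank`),
  emulating cross-platform scale differences. Distortions never change
  within-sample orderings, which is precisely the invariance the method
  claims — and the test suite asserts bit-identical indicators, scores,
  classifications, AUCs and log-rank p-values across all four.

Because the generator satisfies proportional hazards exactly and plants
independent genes, passing tests demonstrate correctness of the machinery
and recoverability of planted signal under the stated conditions — they do
not demonstrate that four-pair signatures generalize on real cohorts, where
correlation structure, non-proportional hazards and small samples all bite.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` use: 20 cohorts x 4 distortions
(n = 60) for the invariance sweep; 50 seeds at n = 500 with a 30-gene panel
(435 pairs before filtering) for planted-signature recovery; 100–200 null
replicates at n = 200 with a 10-gene panel (45 pairs) for calibration; and
a single n = 300 cohort for the end-to-end CLI run. These sizes give
Monte-Carlo error comfortably below the asserted tolerances while keeping a
full run in the low minutes on one core.

## Known limitations

* Selection inference is ignored by design, as in the construction this
  package reproduces: screening and stepwise selection on the same cohort
  overfit, and the honest performance estimate comes from *frozen*
  signatures on independent cohorts.
* The screen's raw $p < \alpha$ threshold performs no multiplicity control;
  with thousands of pairs the expected number of false candidates is
  $\alpha \times$ pairs. The stepwise stage prunes but does not eliminate
  them.
* `fit_cox` covers plain right-censored data only — no time-varying
  covariates, stratification or frailty.
* Gene identifiers are taken at face value; no symbol mapping is attempted.
* The bundled 81-gene immune panel is a placeholder standing in for a
  commercial immune-profiling panel whose full gene list is not
  redistributed here; it contains the eight signature genes and is
  sufficient for simulation and testing, not a clinical instrument.
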