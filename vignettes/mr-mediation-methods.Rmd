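---
title: "Methods: two-sample MR estimation and mediation decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR estimation and mediation decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The problem

Two respiratory diseases — or any pair of traits with large GWAS —
may be associated for three reasons: confounding, reverse causation, or
a genuine causal effect. Two-sample Mendelian randomization (MR) uses
genetic variants as instrumental variables: a variant robustly
associated with the exposure, inherited at random at conception, should
associate with the outcome *only* through the exposure if the exposure
is causal. `mrmediate` implements the complete workflow for such a
study: instrument selection, harmonization, strength diagnostics, five
causal estimators, pleiotropy/heterogeneity sensitivity analyses,
multivariable MR, and a two-step mediation decomposition that splits a
total causal effect into the part flowing through a candidate mediator
(e.g., blood-cell counts, infections, smoking) and the part that does
not.

Everything operates on GWAS *summary statistics*: one row per variant
with alleles, effect-allele frequency (EAF), beta, standard error,
p-value and sample size, for each trait separately.

## Instrument selection and harmonization

Instruments are variants passing a significance threshold (conventionally
$p < 5\times10^{-8}$; $5\times10^{-6}$ is common when a trait yields few
hits — the threshold is per-trait configuration here). Correlated
variants violate the independence assumed by the estimators' weighting,
so candidates are *clumped*: greedily, the lowest-p unclaimed variant
becomes an index SNP and claims every unclaimed variant within a window
(default 10,000 kb) on the same chromosome whose LD $r^2$ with it
exceeds the cutoff (default 0.001). Ties on p-value break by
(chromosome, position) for determinism.

Two LD conventions are supported and differ deliberately:

* **No LD table** (the default): every within-window pair is treated as
  $r^2 = 1$, i.e. pure distance clumping. This is conservative and
  reproducible without a genotype reference panel.
* **User-supplied LD table**: the table is taken as the authority;
  pairs absent from it are treated as independent ($r^2 = 0$), since
  such tables enumerate the correlated pairs.

Harmonization re-expresses every outcome association relative to the
exposure's effect allele: swapped allele roles flip the beta's sign and
reflect the frequency ($f \to 1-f$); opposite-strand reports are
complemented first. Palindromic variants (A/T, C/G) are unresolvable
from the letters alone; the default policy infers orientation from
minor-allele agreement, dropping any variant whose frequency on either
side falls within 0.08 of 0.5 (an uninformative frequency). The
alternative policy drops all palindromes. Harmonization is an
involution: re-harmonizing an already-harmonized pair changes nothing,
and the test suite asserts this.

## Instrument strength

Per variant, the variance explained in the exposure is

$$R^2 = \frac{2\beta^2 f(1-f)}{2\beta^2 f(1-f) + 2Nf(1-f)\,SE^2},$$

and the instrument-strength statistic is

$$F = \frac{R^2\,(N-k-1)}{k\,(1-R^2)},$$

with $k = 1$ for the per-variant F reported here (a pooled F with
$k$ = number of instruments is available behind a flag). $F \ge 10$ is
the conventional low-bias threshold; weaker instruments are flagged but
never silently removed. Note the frequency factor cancels algebraically
in $R^2$; the formula is computed as written and the cancellation is
asserted numerically in the tests.

## The estimator panel

All estimators consume the harmonized per-variant pairs
$(\hat\beta_{Xj}, \hat\beta_{Yj})$ with outcome standard errors
$\sigma_{Yj}$, and report beta, SE, 95% CI, p and the exponentiated
odds-ratio columns.

* **IVW** — weighted least squares of $\hat\beta_Y$ on $\hat\beta_X$
  through the origin, weights $1/\sigma_{Yj}^2$. Default is the
  multiplicative random-effects variant: the SE is inflated by
  $\sqrt{\max(1, Q/(n-1))}$, which equals the fixed-effect SE in the
  absence of excess heterogeneity and never deflates it. This matches
  prevailing two-sample MR practice; fixed-effect is a flag.
* **MR-Egger** — the same regression *with* an intercept, after
  orienting each variant to $\hat\beta_X \ge 0$. The intercept estimates
  the average directional pleiotropy; the slope is the
  pleiotropy-adjusted effect under the InSIDE assumption. Inference uses
  the t distribution on $n-2$ df with the residual scale floored at 1.
* **Weighted median** — the interpolated weighted 50% quantile of the
  Wald ratios $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with
  normalized weights $1/se_j^2$, $se_j = \sigma_{Yj}/|\hat\beta_{Xj}|$.
  Cumulative weights are assigned at $w_j/2$ offsets (the standard
  weighted-percentile convention; conventions differ, so this is stated
  explicitly). Consistent when valid instruments carry $\ge$ 50% of the
  weight.
* **Weighted / simple mode** — the argmax of a normal-kernel density
  over the ratios, bandwidth = `bandwidth_factor` × a modified Silverman
  rule $0.9\min(\mathrm{sd},\mathrm{mad})\,n^{-1/5}$, evaluated on a
  2000-point grid spanning the ratio range padded by one bandwidth. The
  grid makes the argmax deterministic and resolution-bounded; tests
  compare it against a 10× finer independent grid.

Median and mode SEs come from a seeded parametric bootstrap (default
1000 replicates): both betas are resampled from their normal sampling
distributions and the point estimate recomputed. `n_boot = 0` skips the
bootstrap and returns the point estimate with `NA` uncertainty — used
by the large replicate studies in the test suite where only point
estimates are averaged.

With fewer than three variants only fixed-effect IVW is computable; the
panel reports the other methods as explicit not-computable rows rather
than omitting them.

## Sensitivity analyses

* **Cochran's Q** on the ratio scale (IVW; $df = n-1$) or from the
  Egger residuals ($df = n-2$); $p < 0.05$ flags heterogeneity but
  never triggers automatic action. Q on the ratio scale is
  algebraically the weighted RSS of the origin-constrained fit, and the
  tests assert this identity numerically.
* **Egger intercept test** — the intercept row of the same fit that
  produces the Egger slope (single source of truth).
* **Leave-one-out** — IVW re-estimated with each variant excluded;
  exclusions that move the estimate outside the full-data 95% CI are
  flagged. Note the flag is deliberately conservative under the
  random-effects model, because a gross outlier inflates the very CI it
  is compared against; for outlier hunting the fixed-effect CI is the
  sharper choice and MR-PRESSO is the dedicated tool.
* **MR-PRESSO-style global/outlier/distortion tests** — each variant's
  observed residual sum of squares (RSS) is its squared,
  variance-standardized deviation from the leave-that-variant-out IVW
  prediction. The global RSS is compared against seeded parametric
  simulations under the no-pleiotropy model (default 1000); per-variant
  empirical p-values are Bonferroni-corrected at the significance level
  (default 0.05) to flag outliers; the distortion test compares the
  observed all-vs-corrected estimate shift against the shift from
  removing the same number of variants at random. With zero flagged
  outliers the corrected estimate *is* the plain IVW estimate and the
  distortion test is reported as not applicable. The implementation is
  authored from the algorithmic definition above; empirical p-values
  use the add-one convention $(\#\{\cdot\}+1)/(n_{sim}+1)$, so the
  minimum attainable p is $1/(n_{sim}+1)$.

## Multivariable MR and mediation

Multivariable MR regresses the outcome betas on the matrix of exposure
betas (no intercept, weights $1/\sigma_Y^2$); each coefficient is a
direct effect conditional on the other exposures. The instrument set is
the union of each exposure's clumped significant variants, harmonized
across all tables to the first exposure's effect allele (an
exposure-only instrument policy is available in configuration). SEs use
the weighted normal equations with the residual scale floored at 1,
mirroring the univariable IVW convention. A collinear non-primary
exposure yields an `NA` coefficient with a warning naming it — this
also covers the degenerate all-zero-beta column, where the fit must
reduce to univariable IVW on the remaining exposure; only a collinear
*primary* exposure is a hard error.

The two-step mediation decomposition, all on the log-odds scale where
the arithmetic is additive:

* total effect $\beta_{XY}$: univariable IVW of exposure on outcome;
* direct effect $\beta_{XY1}$: the exposure coefficient from MVMR with
  the mediator;
* $\beta_{XZ}$: univariable IVW of exposure on mediator;
* $\beta_{ZY}$: the mediator coefficient from the same MVMR fit;
* indirect effect, both ways: the product $\beta_{XZ}\beta_{ZY}$ with
  delta-method SE
  $\sqrt{\beta_{XZ}^2 se_{ZY}^2 + \beta_{ZY}^2 se_{XZ}^2}$, and the
  difference $\beta_{XY} - \beta_{XY1}$ (an exact identity against
  total minus direct);
* proportion mediated = product-indirect / total, reported as
  non-interpretable when the two disagree in sign or the total is
  numerically zero ($|\beta_{XY}| < 10^{-12}$).

Both indirect forms are always reported because published mediation
analyses differ in which they quote. No CI is attached to the
proportion by default; a bootstrap CI is available behind a flag.
Odds ratios are exponentiated only at the reporting layer.

The study pipeline admits a mediator to the decomposition only with
causal support in both steps: step-1 IVW $p$ and step-2 MVMR mediator
coefficient $p$ below `mediator_alpha` (default 0.05, configurable).

## What the synthetic generator emulates — and what it does not

`simulate_pair()` draws, per variant: EAF uniform on [0.05, 0.95]; a
true exposure effect $\gamma_j$ from a positive-truncated
Normal(0.08, 0.02); the analytic standard error
$1/\sqrt{2N f(1-f)}$ of a standardized-trait GWAS; observed betas with
exactly that sampling noise; and pleiotropy $\alpha_j$ per model (none,
balanced, directional, or correlated-with-strength for InSIDE
violation) on a configurable fraction of variants. The true outcome
effect is $\beta\gamma_j + \alpha_j$. Defaults — 50 instruments, GWAS
sample sizes of 450,000 — were chosen once as a realistic large-biobank
design whose per-variant F statistics span roughly the range seen in
published respiratory-trait MR (tens to low thousands).
`simulate_mediation_triple()` composes effects along the
X → Z → Y graph with distinct instrument sets for exposure and
mediator, and records the generating total, direct, indirect effects
and proportion mediated.

What passing tests on these data *show*: the estimators implement their
defining equations (oracle equivalence), are calibrated when their
assumptions hold (type-I error, CI coverage, mean Q ≈ df), recover
known effects and known pleiotropy, and the decomposition recovers the
generating mediation structure.

What they do *not* show: behaviour under LD between instruments (the
generator spaces variants beyond the clumping window; clumping is
tested with synthetic LD tables instead); binary-trait liability-scale
effects (SEs use the standardized-trait approximation; liability
scaling is declared out of scope); winner's-curse selection bias
(generated instruments are all genuinely strong); and sample overlap
between the two GWAS.

## Numerical and design choices

* P-values: normal approximation for IVW/MVMR and the bootstrap-based
  estimators; t on $n-2$ df for both Egger coefficients. CIs are
  $\beta \pm 1.96\,se$ (t-quantile for Egger).
* All stochastic procedures (bootstraps, PRESSO simulations, the
  generator) take explicit seeds and restore the caller's RNG state;
  identical seeds give bit-identical results, asserted in tests.
* Simulation sizes in the test suite (e.g. 1000 null replicates for
  calibration, 200 for recovery, 100 for mediation) were sized to make
  Monte-Carlo error a small fraction of the tolerance being asserted.
* Degenerate inputs: a zero exposure beta is a hard error naming the
  variant (the Wald ratio is undefined); identical ratios give Q = 0
  and an exact mode/median; empty instrument sets warn at selection and
  error at estimation.
* Table output uses full round-trip precision (`%.17g`, scientific
  below $10^{-4}$) so that write → read is value-identical; the run
  manifest carries an FNV-1a hash of the configuration so reruns are
  verifiably identical and any config change is visible.
* The clump window default follows the widely used 10,000 kb
  convention for the 0.001 $r^2$ cutoff; both are configurable.

## Worked example

```{r example}
sim <- simulate_mediation_triple(
  sim_config(n_snps = 50, true_effect = 0.05, mediator_paths = c(0.2, 0.3)),
  seed = 42)
config <- study_config(
  traits = list(bronchiectasis = sim$exposure,
                neutrophils = sim$mediator,
                copd = sim$outcome),
  exposure = "bronchiectasis", outcome = "copd",
  mediators = "neutrophils",
  n_boot = 200, presso_n_sim = 500, seed = 1)
study <- run_study(config)
study$forward$estimates[, c("method", "n_snps", "or", "or_low", "or_high")]
study$mediations$neutrophils$mediation
```

The generating values here are total 0.11, direct 0.05, indirect 0.06
(proportion 6/11 ≈ 0.545), and the decomposition printed above should
sit within sampling error of them.

## Known limitations

Correlated instruments (generalized IVW with an LD matrix),
likelihood-based and Bayesian estimators, Steiger directionality
filtering, radial MR, and network MR with several simultaneous
mediators are out of scope. The mediator admission rule is a screening
heuristic on two p-values, not a joint test. Proxy-variant substitution
for variants missing from the outcome GWAS is not performed — missing
variants are dropped and counted.
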