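---
title: "Methods: twin ACE modeling of longitudinal growth parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin ACE modeling of longitudinal growth parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinace)
```

## The problem

Longitudinal twin cohorts in developmental neuroimaging measure the same
children repeatedly (here: up to three biennial MRI waves between ages 7
and 14) and ask how much of the variation in brain structure — and in its
*rate of change* — is attributable to genes versus environment. The
classical design compares monozygotic (MZ) twins, who share all of their
segregating genes, with same-sex dizygotic (DZ) twins, who share about
half. `twinace` implements that analysis as a pipeline: per-subject
growth parameters, zygosity-specific within-pair correlations, a
maximum-likelihood ACE variance decomposition with profile-likelihood
confidence intervals, reporting rules, and aggregation — together with a
synthetic cohort generator that makes every stage testable without access
to restricted subject-level data.

## The ACE model and its likelihood

A twin pair's phenotypes are modeled as bivariate normal with a common
mean $\mu$ and covariance

$$\Sigma_g \;=\; \begin{pmatrix} a^2 + c^2 + e^2 & \rho_g\,a^2 + c^2 \\
\rho_g\,a^2 + c^2 & a^2 + c^2 + e^2 \end{pmatrix},
\qquad \rho_{MZ} = 1,\; \rho_{DZ} = \tfrac12 ,$$

where $a^2, c^2, e^2 \ge 0$ are the additive-genetic, shared-environment,
and unique-environment (including measurement error) variance components.
The cross-twin correlation of C is fixed at 1 for both zygosity groups —
all pairs here share a household — and the cross-twin correlation of E is
fixed at 0. The latter deserves a note: with only two zygosity groups, a
freely estimated cross-twin correlation for E is not identified (it is
exchangeable with C's contribution to the within-pair covariance), so the
package uses the standard identified specification. This is the one place
where the package deliberately resolves an ambiguity in how such models
are sometimes described.

**Fitting.** The likelihood depends on the data only through per-zygosity
sufficient statistics $(n, \sum x, \sum x^2, \sum x_1 x_2)$, and for
fixed implied correlations the maximizing $\hat\mu$ (a
$1/(1+\rho_g)$-weighted mean) and $\hat\sigma^2$ (the mean Mahalanobis
quadratic form) are closed-form. Fitting therefore reduces to a 2-D
search over the standardized simplex, parameterized as
$t = a^2/(a^2+c^2+e^2)$ and $u = c^2/(c^2+e^2)$ on $[0,1]^2$ — a
parameterization chosen over signed path coefficients to avoid sign-flip
degeneracy. The optimizer is L-BFGS-B from five starts, always including
the Falconer moment initializer $a^2_0 = 2(r_{MZ}-r_{DZ})$,
$c^2_0 = 2r_{DZ}-r_{MZ}$ clipped to the simplex, followed by a
Nelder-Mead polish. Phenotypes are z-scored on the pooled pair sample
first; the standardized fractions are invariant to this, it merely
conditions the search. Implied correlations are capped at $1 - 10^{-7}$
so that degenerate data (e.g. literally identical MZ values) yield a
finite optimum at the cap instead of an unbounded likelihood, and
non-positive-definite proposals return a large finite deviance so
optimizers never see `Inf`.

**Confidence intervals.** The 95% CI of a standardized component is the
set of values whose profile deviance (re-minimized over $\mu$,
$\sigma^2$, and the split of the remaining variance) lies within
$\chi^2_1(0.95) = 3.841$ of the minimum, located by root-finding on each
side. Published tables in this field print a boundary marker ("NA")
instead of a numeric lower bound when a component is estimated at zero;
the package mirrors that: a bound is `NA` + boundary flag when the point
estimate itself sits on the boundary, and exactly 0 (or 1) with the flag
when the profile stays under the cutoff all the way to the boundary.

## Growth-parameter extraction

Group-level age trends use the linear mixed model
`value ~ age_c * sex + zygosity + (1 | family) + (1 + age_c | child)`
fitted by REML with `lme4`, with age centered at the reference age
(default 7.02 years, the minimum age of the emulated design) so the fixed
intercept is the expected phenotype at that age. Singular random-effect
fits are refitted without the random slope and flagged. Inference on
fixed effects uses Wald z statistics; small-sample denominator-df
corrections (Satterthwaite, Kenward–Roger) are intentionally out of scope
and documented as a simplification.

Per-subject parameters are ordinary least squares per child: the
intercept is the fitted value at the reference age and the slope the
coefficient per year. Children observed once contribute no slope. Their
intercept is ambiguous — a raw value at age 9 is not a value at age 7 —
so two strategies are provided: `"adjusted"` (default; the observed value
minus the *group* fixed-effect slope times the age offset, which removes
the mean age trend without inventing subject-level slope information) and
`"raw"`. Neither is asserted to be what any particular published analysis
did, since that is typically unstated. Children whose observations all
share one age have an undefined slope and are flagged and excluded from
slope analyses. Shifting the reference age by $\delta$ changes every
intercept by exactly $\text{slope}\times\delta$; this identity is tested
to $10^{-12}$.

## Twin correlations and the reporting rules

Within-pair Pearson correlations are computed per zygosity on complete
pairs only, with twin 1/twin 2 assigned deterministically by ascending
child ID (a single-entry correlation; Pearson on a deterministic ordering
keeps runs reproducible, and the likelihood downstream is
exchange-symmetric anyway). The MZ–DZ difference is tested with the
Fisher r-to-z statistic
$z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2)\big/
\sqrt{1/(n_1-3) + 1/(n_2-3)}$, two-sided; the directional requirement
$r_{MZ} > r_{DZ}$ is enforced in the reporting rules rather than by a
one-sided test. No covariate residualization is applied before
correlating — correlations are taken on the extracted parameters
directly.

Components are *reported* by a three-step rule: (1) A when the MZ
correlation is significantly higher than the DZ correlation; (2) the A+C
pattern when both correlations are significant but not significantly
different; (3) any component whose CI excludes zero. Rows where neither
correlation reaches the threshold are not reported. The decision records
which steps fired, and is monotone: raising a CI lower bound above zero
can only add components.

Multiple testing across correlated phenotypes uses a Sidak-type
threshold $1-(1-\alpha)^{1/M_\text{eff}}$ with
$M_\text{eff} = k^{\,1-\bar r}$, where $\bar r$ is the mean pairwise
correlation among the phenotypes of one morphological dimension. This
formula was chosen for its limiting behavior — plain Sidak at
$\bar r = 0$, no correction as $\bar r \to 1$ — because the commonly
cited online calculators for "Sidak corrected for correlated variables"
do not document a reproducible formula; published thresholds computed
with such tools are therefore not asserted in tests, and the formula is
pluggable.

## Aggregation and the bundled reference table

`aggregate_means()` averages the standardized components over reported
rows within groups (network, region, dimension, dimension-within-network,
hemisphere), separately for intercepts and slopes, expressed as whole
percents with ties rounded up; groups without reported rows carry an
explicit absent marker, never zero.

The package ships a transcription of a published reference table from a
longitudinal twin study of brain structure: 72 rows (7 cortical regions
× thickness and surface area × 2 hemispheres, 4 subcortical regions ×
volume × 2 hemispheres, each for intercept and slope) with printed
correlations, z statistics, ACE estimates, and CI bounds, plus a
`reported` flag transcribed from the source's results text. Two kinds of
internal inconsistency in the source are preserved deliberately: rows
where the printed significance stars and the results text disagree are
flagged `text_table_conflict` (the text is encoded, as the downstream
summary table follows it), and summary cells that are arithmetically
inconsistent with the mean of their reported rows (isolated typos, E
cells evidently printed as 100−A−C from rounded A and C, and hemisphere
rows whose row set is not derivable) are enumerated in the acceptance
test with their recomputed values frozen. 34 of the 56 published summary
cells reproduce exactly under the package's rounding rule; the tests
assert exact equality there and the frozen recomputed values elsewhere.

## The synthetic cohort generator

The generator draws, per family: zygosity (MZ with probability 0.53),
sex (male with probability 0.5, shared by both twins — same-sex pairs
only), wave ages, and a per-child number of completed waves; and per
child: latent intercepts and slopes with the ACE covariance structure
(A bivariate normal with cross-twin correlation 1 or 0.5, C identical
within a pair, E independent — the standard generative assumption; the
components' distributions are otherwise unconstrained by the designs it
emulates). Observed rows are
`value = intercept + slope·(age − 7.02) + sex_effect·male + noise`.

Design choices worth knowing:

- **Ages follow a longitudinal revisit model.** A child's wave-1 age is
  drawn from N(7.97, 0.67²) and later waves add gaps of 2.04 and 2.27
  years with SDs derived from the per-wave marginal SDs
  ($\sqrt{sd_k^2 - sd_{k-1}^2} \approx$ 0.12 and 0.29 years). Drawing
  wave ages independently instead would allow within-child gaps near
  zero — inconsistent with a biennial design, whose near-constant
  per-wave SDs imply strongly correlated ages — and would make two-point
  intercept extrapolation arbitrarily noisy. Both twins of a family share
  their wave ages, as for twins scanned at the same visit. Draws are
  rejected until each age lies within 3 SD of its wave mean and ages
  strictly increase.
- **Dropout is monotone and MCAR**: a child completing $k$ waves has
  waves $1..k$, with completion probabilities 118/206/161 out of 485,
  independent of the phenotype. Real attrition is unlikely to be fully
  random; the generator makes no attempt to model informative missingness.
- **Defaults** are on a cortical-thickness-like scale: mean intercept
  3 mm, mean slope −0.02 mm/year, latent SDs 0.15 mm and 0.02 mm/year,
  within-subject measurement noise 0.05 mm per wave, intercept ACE
  .35/.15/.50 and slope ACE .20/.10/.70 (mid-range of published estimate
  tables), sex effect 0 so twin statistics are clean unless configured.
- **Multi-measure cohorts share one pedigree**
  (`generate_cohort_set()`): zygosity, sex, ages, and completion are
  common across measures, each measure's latents coming from an
  order-stable sub-stream of the master seed.

What passing tests on generated data do *not* show about real data: the
generator has no informative dropout, no scanner or site effects, no
non-additive (dominance) genetic variance, no opposite-sex pairs, no
age-varying heritability, and linear subject-level growth by
construction. Recovery results on it validate the estimator chain, not
those substantive assumptions.

A scientifically important and intended consequence of the design does
show up in simulations: heritability estimated from *extracted* growth
parameters is attenuated relative to the latent truth, because
per-subject OLS noise loads on E. That matches the standard
interpretation of E as unique environment *plus measurement error*, and
is why slope heritabilities (noisier extraction) run lower than intercept
heritabilities at equal latent values.

## Numerical choices and problem sizes

- Deviance cutoff for 95% CIs: 3.841 ($\chi^2_1$); CI level fixed at 95%.
- Implied-correlation cap $1-10^{-7}$; non-PD deviance $10^{10}$;
  boundary flags at $10^{-4}$ of a standardized component.
- Rounding of percent summaries: half-up (`floor(x + 0.5)` with a
  $10^{-9}$ epsilon against binary ties).
- Optimizer: L-BFGS-B (5 starts incl. Falconer) + Nelder-Mead polish,
  `reltol 1e-12`; profile CIs by `uniroot` at tolerance $10^{-6}$ with an
  inner 1-D `optimize` over the remaining-variance split.
- Pipeline sub-seeds come from an affine hash of the master seed, kept
  below $2^{31}$, so stages and measures are reproducible independently
  of execution order.

The test suite's simulation sizes, chosen to pin each property down
within Monte-Carlo error while keeping a full run around half a minute:
latent-correlation checks at 2,000–5,000 pairs per zygosity; ACE
recovery at 5,000 pairs (single fit) and 500 replicates × 250 pairs
(bias ≤ 0.02, profile-CI coverage within [92%, 98%]); null calibration
of the Fisher test at 1,000 replicates (rejection 5% ± 1.5%); oracle
equivalence on 20 instances of ≤ 60 pairs against a 200×200 simplex grid
search with two local refinements (the refinements are needed because a
bare 200×200 grid's resolution exceeds the $10^{-4}$ deviance agreement
being asserted); mixed-model Wald coverage at 100 replicates × 60
families.

## Known limitations

- Only the full ACE model is fitted — no AE/CE/E submodel selection, no
  dominance (ADE), no sex-limitation, and no bivariate/Cholesky
  longitudinal models.
- Half-missing pairs are dropped (complete-pairs analysis); there is no
  full-information treatment of singletons in the twin model.
- Wald z inference for the mixed model is anti-conservative in small
  samples relative to Satterthwaite/Kenward–Roger corrections.
- Subject-level growth is linear by construction; with at most three
  timepoints, curvature is not identifiable per child anyway.
- The printed thresholds of external "correlated-variables Sidak"
  calculators cannot be reproduced without their undocumented formula;
  only this package's own formula is tested.
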