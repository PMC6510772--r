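---
title: "Methods: combining-ability analysis of half-diallel trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combining-ability analysis of half-diallel trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(griffing)
```

## The design and the model

A half diallel crosses p parents in all unordered pairs, giving p parents
plus p(p-1)/2 F1 hybrids — p(p+1)/2 *entries* in total (66 for p = 11).
The package analyzes trials where these entries are grown in a randomized
complete block design (RCBD) with r replicates inside each of one or more
environments. Plot values decompose as

$$X_{ijkl} = u + e_i + r_{j(i)} + g_k + g_l + s_{kl}
  + eg_{ik} + eg_{il} + es_{ikl} + \varepsilon_{ijkl},$$

with environment effects $e_i$, replicates within environment $r_{j(i)}$,
general combining abilities (GCA) $g_k$, specific combining abilities (SCA)
$s_{kl}$, their environment interactions, and plot error. Within one
environment the entry means obey Griffing's Method 2 / Model 1 form
$x_{ij} = u + g_i + g_j + s_{ij}$ (parents are the diagonal,
$x_{ii} = u + 2g_i + s_{ii}$).

## Estimation

`estimate_effects()` uses the closed forms. With row sums
$Y_i = x_{i\cdot} + x_{ii}$ and $x_{\cdot\cdot}$ the total over distinct
entries:

$$\hat u = \frac{2 x_{\cdot\cdot}}{p(p+1)},\qquad
  \hat g_i = \frac{1}{p+2}\Big(Y_i - \frac{2}{p} x_{\cdot\cdot}\Big),\qquad
  \hat s_{ij} = x_{ij} - \frac{Y_i + Y_j}{p+2}
    + \frac{2 x_{\cdot\cdot}}{(p+1)(p+2)}.$$

These are exactly the constrained least-squares solution under
$\sum_i g_i = 0$ and $\sum_j s_{ij} + s_{ii} = 0$ for every i; the model is
saturated, so $\hat u + \hat g_i + \hat g_j + \hat s_{ij} = x_{ij}$ holds
cell by cell. The test suite checks both facts against an independent
linear-system oracle on random tables (tolerance 1e-9).

`partition_genotype_ss()` computes the Method-2 sums of squares on the
entry-mean basis and scales by r to the plot basis; by construction
SS(GCA) + SS(SCA) equals the RCBD genotype SS (checked against `stats::aov`
to 1e-8 relative). `combined_anova()` partitions the pooled genotype SS the
same way on entry means pooled over environments, and obtains the
interaction partitions from the pooling identity
SS(GCA x E) = sum of per-environment SS(GCA) minus pooled SS(GCA)
(analogously SCA x E).

Degrees of freedom are the design closed forms; for the 11-parent,
2-environment, 2-replicate layout the combined table is
(1, 2, 65, 10, 55, 65, 10, 55, 130).

## Tests, standard errors and LSDs

Model 1 treats genetic effects as fixed, so every ANOVA F statistic is
formed against the pooled residual; p-values come from the F distribution
and star codes are `**` (p < 0.01), `*` (p < 0.05), `ns`. Effect t tests
and LSDs use the entry-mean error variance
$\hat\sigma^2_{e'} = MS_{error}/r$ with the per-environment error df
$(n_{entries}-1)(r-1)$ — 65 for the reference design. This df choice is the
one that reproduces the published GCA LSD of 2.45 exactly (the pooled
130-df alternative does not), so the same convention is used for the effect
stars; a `df_error` argument makes it adjustable. Contrast variances are
the Method-2 forms $2\sigma^2_{e'}/(p+2)$ (GCA pairs),
$2(p+1)\sigma^2_{e'}/(p+2)$ (SCA sharing a parent) and
$2p\,\sigma^2_{e'}/(p+2)$ (disjoint SCA). Individual effect variances are
not transcribed from tables: they are computed exactly from the coefficient
vector of the estimator's linear map, and a property test confirms the
contrast closed forms against that computation.

## Variance components and heritability

Equating random-model expected mean squares gives

$$\hat\sigma^2_{GCA} = \frac{MS_{GCA} - MS_{SCA}}{r(p+2)},\qquad
  \hat\sigma^2_{SCA} = \frac{MS_{SCA} - MS_{error}}{r},$$

with $\sigma^2_A = 2\sigma^2_{GCA}$ and $\sigma^2_D = \sigma^2_{SCA}$ under
this design. Baker's ratio $2\sigma^2_{GCA}/(2\sigma^2_{GCA} +
\sigma^2_{SCA})$ summarizes additive versus dominance control.
Heritabilities are entry-mean based:
$h^2_b = (\sigma^2_A + \sigma^2_D)/(\sigma^2_A + \sigma^2_D + \sigma^2_E/r)$
and $h^2_n$ with $\sigma^2_A$ in the numerator, where $\sigma^2_E$ is the
plot-basis residual MS of the same environment (this convention reproduces
the published h² values, e.g. 42.78/(42.78 + 62.51 + 19.54/2) = 0.37).

Negative component estimates are *reported as computed* with a
`truncated` flag rather than being set to zero: truncation would bias the
Monte-Carlo calibration tests, and the flag still alerts users. Downstream
ratios and heritabilities use the raw values and warn.

Component significance reuses the mean squares: GCA is tested with
F = MS(GCA)/MS(SCA), SCA with F = MS(SCA)/MS(error). This is the rule
consistent with published tables in which a strongly significant GCA mean
square can still yield a non-significant $\sigma^2_{GCA}$ when the SCA mean
square is large.

## Heterosis

For each hybrid, mid-parent heterosis is $100(\bar F_1 - MP)/MP$ with
$MP = (P_1 + P_2)/2$, and heterobeltiosis is $100(\bar F_1 - BP)/BP$ with
$BP = \max(P_1, P_2)$ — the numerically larger parent regardless of trait
direction, matching the printed formula; direction (e.g. smaller seed
cavities are better) only enters the favorability call, which is strict
(zero is never favorable). The LSDs are
$t\sqrt{3M_e/(2r)}$ (vs MP) and $t\sqrt{2M_e/r}$ (vs BP), applied to the
trait-unit deviations; their ratio is $\sqrt{4/3}$ identically. The error
df is per-environment (65) by default, consistent with the effect LSDs;
whether published analyses used 65 or the pooled 130 is not stated, so the
argument is exposed. Significance at the LSD boundary uses strict
inequality (ties are measure-zero).

Fisher LSD mean comparisons use $t\sqrt{2MS_{error}/r}$. Because all entry
means share one standard error, non-significance groups are intervals of
the sorted means; the compact letter display labels the maximal intervals
(insert-and-absorb). The pairwise boolean matrix is the tested contract;
letters are presentation.

## The synthetic-trial generator

`simulate_diallel()` draws every term of the combined model as independent
Gaussians at user-chosen variances and sums them per plot, returning the
drawn truth for recovery tests. Choices that matter:

* GCA effects are centered to sum exactly to zero (and GCA x E within each
  environment) so the finite-sample truth satisfies the estimator's
  identifiability constraint; SCA draws are symmetric, one draw per
  unordered pair including the parental diagonal, and are *not* centered —
  with this scheme the component estimators are unbiased for the generator
  variances (verified by the 200-replicate recovery test).
* One global seed feeds fixed per-component substreams, so changing r does
  not reshuffle the genetic effects.
* `diallel_preset(trait, environment)` returns single-environment configs
  at the variance magnitudes reported for a published 11-parent melon
  salinity half-diallel (10 fruit traits, non-saline and saline irrigation,
  r = 2): `var_gca` and `var_sca` are the reported GCA/SCA variance
  components, `var_error` the residual MS, and the grand mean is
  back-calculated from the reported CV as $100\sqrt{MS_{error}}/CV$ (40.2
  t/ha for non-saline fruit yield, 23.5 under salinity — the realistic
  yield decline). Interaction variances default to zero because each
  preset describes one environment.

What a green simulation test does *not* establish: the generator is
Gaussian, balanced and additive-dominance only — no epistasis, no
reciprocal or maternal effects, no spatial trend, no missing plots. Results
on real trials with those features are outside what the calibration tests
certify.

## Numerical and design choices

* Balance is required, not repaired: the closed forms assume it, and
  imputation would silently change every SS. Unbalanced input fails with a
  report naming the missing cells. Missing values are rejected.
* Parent indexing is 1-based (`P1..Pp`) in all reports.
* Reported tables round to 2 decimals by default; `summary.json` keeps
  full precision, and rendering never recomputes — every rendered number
  is the rounding of a summary value.
* Tolerances: effect-oracle equivalence 1e-9; SS identities 1e-8 relative.
* t and F quantiles come from R's distribution functions, never from
  printed critical-value tables.
* The Monte-Carlo recovery criterion uses a 99.9% band
  ($3.3\,\hat\sigma/\sqrt{200}$) so the three simultaneous component checks
  keep a small suite-level false-alarm rate; the SCA type-I check uses the
  stated 5% ± 2% band over 500 null replicates.

## Known limitations

Griffing Methods 1, 3 and 4 (reciprocals, F1-only sets), mixed-model REML
for unbalanced data, lattice adjustment, epistatic variance, and standard
errors for heritability estimates are out of scope.
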