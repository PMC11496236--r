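---
title: "Two-step latent class and latent Markov analysis of psychiatric panel data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step latent class and latent Markov analysis of psychiatric panel data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lcpanel` implements a two-stage analysis of panel surveys with binary
diagnostic indicators, of the kind used to study the joint course of mood and
anxiety disorders in general-population cohorts: eight 12-month DSM
diagnoses (major depression, dysthymia, bipolar disorder, panic disorder,
agoraphobia, social phobia, specific phobia, GAD) measured on the same
respondents across four waves roughly three years apart, with monotone
attrition. This vignette describes the models, the estimation choices and
their rationale, the synthetic cohort generator used for validation, and the
known limitations.

## The measurement model

Stage one is a latent class analysis of the *pooled* person-waves: every
observed wave of every respondent is treated as a case, so a cohort of 6,646
respondents observed 6646/5303/4618/4007 times yields 20,574 records. Given
class $c$, the $J$ binary indicators are conditionally independent
Bernoulli draws:

$$
P(\mathbf y \mid c) \;=\; \prod_{j=1}^{J} p_{cj}^{\,y_j}\,(1-p_{cj})^{1-y_j},
\qquad
\mathrm{logit}\, p_{cj} \;=\; \beta_{cj} + b\,\delta_j ,
$$

where $b \in \{0,1\}$ flags the baseline wave. The $\delta_j$ offsets absorb
*measurement non-invariance* of the baseline assessment: a lifetime-frame
interview at wave 0 detects more 12-month disorder than the interval-frame
follow-up interviews, so baseline records show elevated indicator prevalence
within every class. Letting the baseline flag shift the indicators — and
only the indicators, never class membership — keeps the class definitions
comparable across waves without letting the instrument artifact masquerade
as prevalence change. The offset is shared across classes per indicator; a
class-specific offset would be weakly identified for classes holding well
under 2% of the records.

Estimation is EM on unique response patterns (at most $2^{J+1}$
pattern-by-baseline groups, so the per-iteration cost is independent of the
record count), with the M-step for $(\beta_{\cdot j}, \delta_j)$ a small
Newton step with step-halving — a generalized EM whose log-likelihood is
non-decreasing by construction. Emission probabilities are kept inside
$[10^{-6}, 1-10^{-6}]$ to avoid degenerate log-likelihoods. Convergence is
declared when the relative log-likelihood change falls below $10^{-8}$
(at most 5,000 iterations).

### Multiple random starts

Mixture likelihoods are multimodal, and this one particularly so: one class
holds ~94% of the mass, and a large basin of attraction exists in which a
spurious class splits off a sliver of the dominant class. The protocol runs
64 random starts for 250 initial EM iterations each and continues the best
to convergence. Starting posteriors are drawn per pattern from a Dirichlet
with concentration 0.1 rather than a flat Dirichlet: flat draws produce
near-uniform posteriors whose first M-step yields almost identical mixed
parameters for every start, so all starts fall into the same (often
degenerate) local maximum. Sharp draws behave like random hard partitions
and explore genuinely different basins; in our experiments they recover
solutions 20–40 log-likelihood units better on roughly a third of simulated
cohorts. Classes are relabeled by descending mixing weight (ties broken on
the first indicator's emission probability), so labels are deterministic.

## Model selection and diagnostics

`select_k()` compares class counts by AIC ($-2\ell + 2p$), BIC
($-2\ell + p\log n$) and AIC3 ($-2\ell + 3p$), the smallest value preferred.
The BIC sample size is the number of pooled records by default (each wave is
a case in this stage); a flag switches to respondents. That choice is
defensible only if within-person clustering barely inflates the variance of
the stage-one estimates, which is exactly what `design_effect()` checks: the
ratio of cluster-robust (sandwich, clustered on respondent) to naive
variance of the class-proportion parameters. On cohorts of this structure
it stays close to 1.

Two parametric bootstrap tests complement the criteria. The goodness-of-fit
test simulates from the fitted model, refits, and compares the
likelihood-ratio statistic $L^2$ over response patterns; the
likelihood-ratio test for $K$ vs $K-1$ classes simulates under the smaller
model. Both use the add-one rule $p = (1 + \#\{T_b \ge T\})/(B+1)$, so no
p-value is ever exactly zero, and bootstrap refits use a reduced budget
(8 starts × 50 iterations, then continuation at tolerance $10^{-6}$) —
full-budget refits change none of the decisions but multiply the cost.
Non-convergent replicates are dropped, with a hard error beyond 20%.

Bivariate residuals (BVRs) compare the observed two-way table of each
indicator pair — or of an external variable against each indicator — with
the model-expected table, as Pearson $X^2$ divided by the table's degrees of
freedom; expected counts come from the posterior-weighted class composition.
Pairs above 3–4 signal violated local independence; the wave number
(0–3) crossed with the indicators probes time-invariance of the classes.
One calibration caveat is documented openly: under this definition the
*maximum* wave-by-indicator BVR on a correctly specified cohort of this
scale straddles 1 (each table's statistic has mean well below 1, but the
maximum of eight does not), so "every wave BVR below 1" is a stricter bar
here than it appears to be in software whose unpublished BVR normalization
concentrates lower. The indicator-pair diagnostic at the conventional
threshold of 3 is unaffected.

## The structural model: a two-step latent Markov chain

Stage two treats each *respondent* as a case and models class dynamics as a
first-order hidden Markov chain: initial distribution $\pi$, a single
time-homogeneous $K \times K$ transition matrix $A$ per inter-wave interval
(per-interval matrices sit behind a flag), and the stage-one measurement
model frozen. Following the two-step logic, the only data summary the
structural stage consumes is the matrix of *class-specific log-densities*
$\log P(\mathbf y_{it} \mid c)$ exported from stage one (with the baseline
offset honored at wave 0). Freezing the measurement model avoids the large
classification error a hard-assignment three-step analysis would commit
with classes this small, and re-importing the exported densities reproduces
stage-two likelihoods exactly.

The likelihood is computed by scaled forward–backward recursions vectorized
across respondents. A missing wave contributes a unit emission term, so the
chain marginalizes over it: it provides no information about the adjacent
transitions, and deleting trailing unit terms leaves the likelihood
unchanged (a property test asserts this, and the forward pass is verified
against exhaustive latent-path enumeration to $10^{-10}$). EM updates
$\pi$ and $A$ only; rows of $A$ remain exactly stochastic at every
iteration. With near-degenerate emissions the estimator reduces, exactly,
to the empirical transition frequencies of the observed chain — a closed
form the tests assert.

Standard errors are cluster-robust sandwich estimates: per-respondent score
vectors from the Fisher identity on a reference-logit parameterization
(staying in the origin class is the reference destination), an observed
information matrix from finite differences of the analytic score, and the
delta method back to the probability scale. They ignore stage-one sampling
uncertainty — the usual, documented limitation of the plain two-step
variance.

Small-sample behaviour deserves a warning. With a class holding 0.6% of a
cohort of 6,646, the rarest origin row of $A$ rests on roughly 126
informative respondents. In simulation the ML estimator of that row carries
bias of a few percentage points even when the measurement model is fixed at
its true values, and plug-in measurement error adds more; the common rows
are recovered to within about half a percentage point. Estimates for rare
origin classes should be read with their standard errors, not as point
truths.

## Covariates

`profile_classes()` describes classes by background characteristics:
posterior-weighted class-specific means (proportions for binary
covariates), cluster-robust SEs, and a Wald test of all-classes-equal with
$K-1$ degrees of freedom; records missing a covariate are dropped for that
covariate only. `transition_logit()` re-estimates the latent Markov model
with the transition logits linear in a single covariate measured at wave
$T$, predicting the transition to $T+1$; staying is the reference
destination, so a coefficient is the log-odds shift of one specific move
against remaining in place. One covariate per run, matching the exploratory
one-at-a-time design; missing values are mean-imputed (which leaves the
covariate mean exactly unchanged); time-fixed covariates (sex, childhood
abuse) carry their wave-0 value forward. Because twelve transition
coefficients are tested per covariate, effects are flagged at a strict
$p < 0.001$ and, separately, at $p < 0.01$ — both thresholds appear in the
source analyses, so both are reported rather than silently resolving the
discrepancy. Intercepts are re-estimated in every covariate run rather than
fixed from the covariate-free fit; either convention is defensible and
re-estimation is the standard likelihood-based choice. With slopes constrained to zero the
implied transition matrix reproduces the covariate-free fit to $10^{-4}$,
and Wald statistics are invariant to affine rescaling of the covariate.

## The synthetic cohort generator

No public data release exists for the motivating cohort, so validation is
by parameter recovery against `simulate_panel()` /
`simulate_pooled()`, whose defaults are calibrated to the published
quantities and define the study conditions:

* class prevalences 94.1 / 3.6 / 1.8 / 0.6% (normalized by their sum, which
  prints as 100.1);
* the published transition matrix, with the few unprinted cells filled by
  row complements: the healthy row's residual 0.5pp split 0.4/0.1 between
  fear and high comorbidity, the depressed-worried row's move to fear set
  to 18.2 by complement with its move to high comorbidity at 5.6, the
  high-comorbidity row's move to depressed-worried set to 11.1 by
  complement, and the fully printed fear row normalized by its sum;
* wave sizes 6646/5303/4618/4007, stored as exact retention ratios so the
  expected pooled record count is exactly 20,574; quota dropout (the
  default) reproduces the wave sizes deterministically, Bernoulli dropout
  is optional, and dropout is monotone and class-independent — the
  estimators assume ignorable missingness, so class-dependent dropout is
  deliberately not the default;
* a baseline logit offset of 0.5 on every indicator, a moderate value
  consistent with "higher prevalence at baseline" since no magnitude is
  published;
* emission probabilities chosen to reproduce the qualitative class
  profiles (healthy: everything ≤ 2%; depressed-worried: depression 0.75,
  GAD 0.35; fear: specific/social phobia 0.65/0.55, panic 0.35; high
  comorbidity: ≥ 0.45 on all but bipolar at 0.30). The true class-specific
  estimates are in unpublished supplementary material, so these are
  explicit stand-ins, never ground truth.

Covariates can be attached with class-conditional distributions, optionally
fed into the transition logits (so injected effects on course can be
recovered), optionally time-fixed, and optionally masked at a missingness
rate. All randomness flows from one master seed through named substreams
(`derive_seed()`), and identical configurations reproduce byte-identical
datasets.

What the generator does *not* emulate: the diagnostic interview's skip
logic and hierarchy-free diagnosis construction (indicators are generated
directly), survey weighting and fieldwork, informative attrition, and any
time-inhomogeneity of the dynamics. Passing recovery tests therefore shows
that the estimators recover the parameters of this idealized data-generating
process at the study's scale — not that the substantive published estimates
are correct.

## Problem sizes used in the validation suite

The recovery experiments average 25 replicate cohorts at full study scale
(20,574 pooled records; 6,646 respondents over 4 waves). The bootstrap
likelihood-ratio calibration uses 200 replicates of a well-separated
two-class cohort of 400 records at $B = 49$; the transition-covariate power
check uses one cohort of 20,000 respondents and the size check 60 null
cohorts of 1,200; the time-invariance diagnostic uses 20 full-scale
cohorts started from the stationary distribution of the default transition
matrix. Oracle checks (path enumeration, closed forms, round trips) run at
toy sizes in seconds.

## Known limitations

* Stage-two standard errors ignore stage-one uncertainty.
* Indicators must be binary; ordinal or nominal items are out of scope.
* The Markov chain is first-order and time-homogeneous by default; no
  mover–stayer mixture, no continuous-time interpretation.
* Transition estimates for origin classes observed in only ~100
  respondents carry visible small-sample bias (see above).
* The BVR normalization is this package's documented definition; absolute
  values are not comparable across software.
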