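---
title: "The canpros risk model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The canpros risk model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(canpros)
```

`canpros` is a segregation-analysis and risk-prediction engine for prostate
cancer families. This vignette documents the model, the numerical choices,
the assumptions baked into the defaults, and what the package's tests do and
do not demonstrate.

## The genetic model

An individual's prostate cancer hazard at integer age $t$ is

$$\lambda(t \mid G, P) \;=\; \lambda_0(t)\, \mathrm{RR}_G(t)\,
  e^{\sigma(t) P},$$

where $G$ ranges over the joint genotypes of four biallelic loci and $P$ is
a standardized polygene level.

* ***BRCA2*, *BRCA1***: dominant, with piecewise-constant age-specific
  carrier relative risks that are *external inputs*, never estimated —
  family data on rare-PV carriers are too sparse for internal estimation.
* ***HOXB13* G84E**: multiplicative per allele, with separate relative
  risks for men born before/after 1930. The boundary year is closed on the
  right: born 1929 uses the earlier cohort, born 1930 the later.
* **Fourth gene**: a hypothetical variant capturing residual familial
  aggregation. The default inheritance is recessive (only homozygotes carry
  the relative risk `rr_rec`); dominant and multiplicative variants are
  available behind `rec_model` so that nested model comparisons
  (`compare_models()`, `lrt()`) can reproduce an inheritance-model
  selection sequence.
* **Polygene**: normal on the log-hazard scale with age-dependent SD
  $\sigma(t) = \sigma_{70}\, r^{t-70}$. The genotype (the level $P$) is
  fixed over life; only its effect scale $\sigma(t)$ changes with age.

Loci are in Hardy–Weinberg and linkage equilibrium; all joint effects are
multiplicative on the hazard scale.

### Polygene discretization

Exact pedigree likelihoods need a finite state space, so the polygene uses
the hypergeometric polygenic model: $2k$ exchangeable binary alleles, count
$i \sim \mathrm{Binomial}(2k, 1/2)$ in the population, standardized values
$(i-k)/\sqrt{k/2}$ (mean 0, variance 1 exactly at every $k$). Transmission
draws $k$ alleles without replacement from each parent, which makes the
offspring mean exactly the midparent mean and leaves the population
distribution invariant under random mating. The segregation variance is
$k/(2k-1)$ of the population variance — the finite-$k$ analogue of the
Mendelian one half, converging as $k$ grows. The default grids are 7 levels
($k=3$) for each polygene part; tests quantify the peeling engine's
exactness at any grid size, and the grid is a resolution parameter, not a
model quantity.

### The PGS decomposition

The measured polygenic score explains a fraction $\alpha$ (default 0.523)
of the polygenic SD. The polygene is therefore split into two independent
discretized sub-components, an *observed* part and a *residual* part, whose
log-hazard loadings are $\alpha\sigma(t)$ and $\sqrt{1-\alpha^2}\sigma(t)$:
the variances add to $\sigma(t)^2$ exactly. A measured PGS value $z$ enters
the likelihood as a Gaussian measurement of the observed-part level,
$z \sim N(v_{\text{obs}}, \tau^2)$ with a small nugget $\tau$ (default
0.2). The nugget makes $P(z \mid \text{polygenotype})$ a proper density on
the discrete grid; its cost is that the marginal PGS variance is
$1 + \tau^2$ rather than 1, a deliberate approximation that is immaterial
at the default value. A conditional-Gaussian formulation without
sub-component grids would be an alternative; the chosen construction keeps
the peeling state space finite and satisfies the stated variance
decomposition, which is the testable contract.

## The incidence constraint

Risk heterogeneity inflates naive penetrances, so $\lambda_0(t)$ is *not* a
free parameter: `constrain()` iterates over ages and sets

$$\lambda_0(t) = \frac{\lambda_{\text{pop}}(t)}
  {E[\mathrm{RR}(G, P, t) \mid \text{unaffected at } t]},$$

updating the genotype distribution among the unaffected by survival
weighting each year. The population-average hazard among survivors then
equals the external incidence table at every age (tests check this to
1e-8 relative). Incidence tables are stratified by age band and calendar
period (or birth cohort); each man's hazard at age $t$ is read from the
stratum of calendar year `birth_year + t` (period mode) or of his birth
year (cohort mode). Coarse age bands are expanded to the internal one-year
grid by constant interpolation, and a diagnosis "at age $a$" contributes
the hazard of $[a, a+1)$.

Risks are cause-specific cumulative risks: **no competing mortality is
applied**, matching how lifetime risks of this kind are usually quoted.
Female relatives carry breast/ovarian phenotypes through externally
supplied penetrance curves per BRCA1/2 carrier class (no polygene), and
those hazards are not re-constrained against female incidence tables — the
female model is a pluggable nuisance component here, kept only so that
female relatives' phenotypes inform the male model through shared BRCA
genotypes. The shipped female curves are illustrative defaults.

## Likelihood, ascertainment, estimation

`peel()` computes the exact log-likelihood of a family by Elston–Stewart
peeling: nuclear families are eliminated from the periphery inward, with
per-component tensor contractions exploiting the factorized transmission
(four loci x two polygene parts). Pedigrees with marriage or inbreeding
loops are rejected at validation rather than loop-broken — an explicit
scope decision; loop-cutting approximations are easy to get silently wrong.
Messages are renormalized to guard underflow. Genetic tests are perfectly
specific; sensitivities default to 0.83 (*BRCA2*), 0.65 (*BRCA1*), 1.0
(*HOXB13*), reflecting truncating-variant panels that miss some PV classes.

Families reach studies because of their phenotypes, so `condition()`
subtracts the log-likelihood of the conditioning data:
`proband_phenotype` conditions on the proband's affection status and ages,
`family_phenotypes` on all members' phenotypes with genotypes and PGS
marginalized. The automatic mapping uses the proband's detection mode —
symptomatic diagnoses condition on the proband phenotype only, while
screen-detected or unknown-mode diagnoses condition on the whole family's
phenotypes, since screening uptake may itself respond to family history.
The `none` scheme exists to demonstrate the bias it causes.

`fit()` maximizes the summed conditioned log-likelihood on a transformed
scale (logit frequencies and PGS fraction, log relative risks and SD
parameters). One-dimensional problems use Brent search; multi-parameter
problems use Nelder–Mead with a BFGS polish and three seeded random
restarts. Convergence tolerance is 1e-6 on the log-likelihood; standard
errors come from the numerical Hessian on the transformed scale, and
boundary estimates (|transformed| > 12) are flagged rather than raised.
When every pedigree is a two-generation nuclear family the likelihood is
evaluated by a vectorized batch path that is bit-compatible with the
general recursion (tested); this is what makes simulation studies with
thousands of families tractable in pure R.

## Prediction and validation

`posterior_states()` clamps the consultand in the peel and renormalizes,
conditioning on him being cancer-free at his current age; `predict_risk()`
averages genotype-specific cumulative risks over that posterior.
`familial_relative_risk()` computes hazard ratios for relatives of affected
index cases by exact summation over two- or three-person joint state
spaces.

For validation cohorts with family-history summaries instead of full
pedigrees, a minimal pedigree (father, mother, listed brothers) is
implied; relatives that are not reported carry **no phenotype assumption**.
Missing diagnosis ages of affected relatives can be filled by
`impute_relative_dx_ages()` from a generational age-offset table (father =
consultand age + 28 by default, clamped to [40, relative's age]), with a
seeded stochastic mode drawing from the population diagnosis-age
distribution.

Validation metrics: a horizon-truncated Harrell concordance (events within
the horizon vs comparators still at risk; ties count one half; bootstrap
CI over subjects, 1,000 seeded resamples by default), Kaplan–Meier
calibration per predicted-risk decile with Greenwood log–log intervals,
and case-capture tables at configurable top-risk quantiles. Recalibration
acts on the cumulative-hazard scale, `risk' = 1 - (1 - risk)^c`; the
multiplier `c` is solved so the recalibrated overall observed/expected
ratio is exactly 1 (its first-order value is the raw O/E ratio), and
subject ranking — hence discrimination — is unchanged.

## The synthetic-data generator

`simulate_families()` and `simulate_cohort()` sample from the *same* model
the likelihood evaluates: founders from the genotype prior, transmission
per component, event times by inverse transform on the annual hazard grid,
ascertainment by rejection (affected proband, plus a young-onset age cut
or a family-history requirement per arm), detection modes from the
configured mixture (defaults 50% symptomatic / 24% screen / 26% unknown).
Each family's random stream derives from `(seed, family index)`, so any
subset is reproducible independently of the total count. Default family
structure: father, mother, the index man, and Poisson(1.5) brothers;
probands born 1920–1950 and censored in 2005, so they are old enough for
realistic acceptance rates under ascertainment. Cohort records default to
baseline ages 45–69 at a 2008 entry with 9–13 years of administrative
follow-up.

What the generator deliberately does **not** emulate: under- or
misreporting of self-reported family history, PSA-testing behavior that
responds to a relative's diagnosis, calendar trends in incidence beyond
what the incidence table encodes, competing mortality, and non-European
ancestry. Passing self-consistency tests therefore demonstrates internal
correctness of the machinery — likelihood, constraint, prediction and
validation code agree with each other and with enumeration oracles — not
that the shipped parameter values are externally calibrated.

## Default parameter values

The polygenic parameters ($\sigma_{70} = 2.13$, $r = 0.989$,
$\alpha = 0.523$) and the test sensitivities are published headline
estimates for this class of model. The remaining defaults — allele
frequencies (BRCA2 0.00102, BRCA1 0.00064, HOXB13 0.0017, fourth gene
0.10), the BRCA age-specific RR curves, the HOXB13 cohort RRs (2.0 / 3.6)
and the recessive homozygote RR (10) — are *assumed*, literature-guided
values chosen once; the parameter file documents them as such. The shipped
incidence fixture is synthetic, shaped like modern UK male registry rates
in 5-year bands (cumulative rate ~0.17 person-years to age 85, i.e. a ~16%
cumulative risk). Scenario outputs under these defaults reproduce
published family-history, PGS and population risk figures closely, while
quantities that hinge directly on the assumed PV inputs (notably BRCA2 and
HOXB13 carrier absolute risks) should be read as illustrative until the
assumed values are replaced by calibrated ones.

## Numerical choices and degenerate inputs

* Ages are integer years throughout; intervals are half-open $[a, a+1)$.
* A locus with allele frequency 0 is collapsed out of the state space
  (point mass on noncarrier), shrinking peeling cost with no model change.
* Missing birth years default to the reference cohort (born 1960).
* Individuals with no phenotype data (missing censor age) contribute a
  likelihood factor of 1 — unknown relatives never penalize.
* `constrain()` raises an error if $E[\mathrm{RR}]$ is not positive
  (degenerate priors), and zero-probability pedigree data (e.g. a positive
  test in a family where the locus is absent) raise an error rather than
  returning `-Inf`.
* Risk-group assignment in calibration and capture tables uses first-tie
  ranking, so groups partition exactly and capture fractions are
  nondecreasing in the quantile.

## Problem sizes used in the test suite

The simulation studies in the tests use 2,000 families for point recovery
of each free parameter, 80 replicates of 400 families for Wald coverage
(the per-replicate size keeps the transformed-scale Wald intervals in
their asymptotic regime; at much smaller sizes the per-replicate standard
errors correlate with the estimation error and the intervals become
conservative), 100 null replicates of 150 families for the
likelihood-ratio calibration,
and a 50,000-man simulated cohort for validation self-consistency; these
sizes give Monte-Carlo errors comfortably inside the asserted bands while
keeping the full suite runnable on a laptop. Scenario and familial-risk
checks run on the full default state space (3^4 x 7 x 7 states).

## Known limitations

* No loop-cutting: consanguineous pedigrees are rejected.
* No competing mortality; predicted "risks" are cause-specific.
* The female breast/ovarian component is a pluggable stub, not a
  calibrated model.
* PV-location-specific BRCA2 risks, more than four major loci, X-linked
  inheritance and grade-specific risks are out of scope.
* The PGS nugget makes the marginal PGS variance 1 + tau^2; standardize
  externally computed scores accordingly.
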