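---
title: "Methods: regional variation in bundled surgical episode payments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional variation in bundled surgical episode payments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bundled payment programs reimburse a single fee for all care tied to an
index surgical admission — the hospitalization itself plus everything
that follows for 90 days: readmissions, post-acute services, and
clinician fees. Whether bundling can compress spending depends on how
much regional variation exists once prices and patient mix are
accounted for. This package implements that measurement pipeline for a
universally insured working-age (18–65) surgical population, at the
resolution of Hospital Referral Regions (HRRs): build 90-day episodes
from claims, split payments into four components, strip wage-index
price differences, adjust for case mix with a multiplicative regional
random effect, shrink each region's estimate by its statistical
reliability, and report inter-quintile variation.

Because real military/commercial claims of this kind are restricted,
the package ships a synthetic claims generator (`sim_config()`,
`simulate_claims()`) whose generative parameters are fully known, so
every downstream stage is testable against ground truth.

## Episode construction

An index admission is an inpatient facility claim carrying a procedure
code from a procedure definition's index code set
(`identify_index_admissions()`), for beneficiaries aged 18–65 at
admission. Five definitions ship by default: primary hip replacement
(PHR), primary knee replacement (PKR), coronary artery bypass grafting
(CABG), lumbar spinal fusion (LSF), and colectomy. The shipped code
sets are illustrative placeholders — real analyses supply their own
code lists via `procedure_definition()` or a YAML config; clinical
validation of code sets is out of scope.

Exclusions are applied first-match in a fixed order so each candidate
carries exactly one reason and tallies are reproducible:

1. dual coverage by another payer (episodes with incomplete payment
   capture);
2. trauma diagnosis on the index claim (PHR/PKR only);
3. multi-level fusion — fusion codes at two or more distinct levels on
   one LSF index claim;
4. non-elective admission for elective-only procedures (see below);
5. admission from a skilled nursing facility, long-term care facility
   or hospice;
6. death before discharge;
7. overlap with an earlier included episode of the same beneficiary.

Two decisions here were genuinely open:

* **Elective-only scope.** Only elective surgery is generally eligible.
  We operationalize this by excluding emergent index admissions for
  PHR, PKR and LSF (reason `non_elective`), while for CABG and
  colectomy emergent status instead enters the case-mix model as
  admission acuity — those are the procedures where urgent presentation
  is a normal part of the case mix rather than a protocol violation.
* **Overlapping episodes.** A qualifying admission that starts inside an
  earlier included episode's 90-day window does not open a second
  episode; it is treated as a readmission of the first and labeled
  `overlapping_episode`. First by admission date wins; ties break by
  claim id.

Windows are fixed day counts: the episode window is days 1–90 after
discharge inclusive, and "six months" of lookback is 183 days,
`[admission − 183, admission − 1]`. Lookback spending is summed from
price-standardized amounts so the covariate carries no regional price
signal. Missing race is imputed from the sponsor's race when available,
else coded `unknown`. Finally, per procedure, HRRs with fewer than five
included episodes are dropped (`filter_small_hrrs()`), since
observed/expected ratios from a handful of cases carry almost no
signal.

## Payment components

Every in-window claim lands in exactly one of four buckets
(`allocate_payments()`):

* **index hospitalization** — the index claim plus facility claims dated
  during the index stay;
* **readmissions** — inpatient facility claims admitted in days 1–90
  after discharge (a stay admitted on day 90 counts in full: episodes
  are attributed by event onset);
* **post-acute care** — rehabilitation, skilled nursing, outpatient
  facility, home health, hospice, durable medical equipment;
* **professional fees** — clinician claims in any setting, kept as one
  undivided category because professional claims cannot be reliably
  split between inpatient and outpatient care.

A claim of unrecognized class is a hard error: silent bucketing would
corrupt the conservation identity (component sums equal window-claim
sums to the cent) that the test suite asserts on every synthetic run.

## Price standardization

Regional payment differences driven by wage indices are removed by
deflating the labor-related share of each payment:

$$\text{std} = \frac{\text{paid}}{\ell \cdot w + (1 - \ell)}$$

with wage index $w$ (1 = national average) joined from the zip–HRR
crosswalk and labor share $\ell = 0.62$ by default (configurable). This
mirrors inpatient-PPS-style standardization. One zip-level index is
applied to all claim classes; a per-class index column is accepted when
present. The synthetic generator applies exactly the inverse inflation,
so standardization recovers pre-inflation amounts to floating-point
accuracy — a round-trip the acceptance suite checks at 1e-9 relative
error.

## Case-mix model and reliability adjustment

Episode cost $y_{ij}$ (episode $i$, region $j$) is modeled with a log
link and a mean-1 multiplicative regional effect:

$$E[y_{ij} \mid u_j] = \exp(x_{ij}^\top \beta)\, u_j, \qquad
u_j \sim \text{Gamma}(\alpha, \alpha), \; \alpha = 1/\tau,$$

so $E[u_j] = 1$ and $\text{Var}(u_j) = \tau$ is the between-HRR
variance of the multiplicative effect. The gamma frailty is the
standard provider-profiling convention and suits right-skewed cost
outcomes. Case-mix covariates are age (linear + quadratic), sex, race,
junior-enlisted sponsor rank (a socioeconomic proxy), Charlson
comorbidity index, log1p prior-six-month payments, and — where the
procedure definition requests them — DRG relative weight (resource-use
intensity), admission acuity, and cancer-vs-non-cancer management for
colectomy.

`fit_casemix_model()` estimates this by an iterative moment /
quasi-likelihood scheme, chosen because it is fully specified,
dependency-light and directly testable (full-likelihood GLMM fitting,
MCMC and standard errors for $\beta$ are non-goals — the model's role
here is point adjustment):

1. given current $\hat u_j$ (init 1), fit a log-link GLM of $y$ on $x$
   with offset $\log \hat u_j$ — gamma family when the outcome is
   strictly positive, a log-link quasi-Poisson estimating equation when
   it contains zeros (payment components routinely do; no log of zero
   is ever taken);
2. $\mu_{ij} = \exp(x_{ij}^\top \hat\beta)$, $E_j = \sum_i \mu_{ij}$,
   $O_j = \sum_i y_{ij}$, $r_j = O_j / E_j$;
3. dispersion $\hat\phi = \frac{1}{N-p}\sum (y - \hat m)^2 / \hat m^2$
   (squared-CV scale, $\hat m$ the full fitted mean) — used for all
   outcome families so the reliability weight below is always on the
   same scale;
4. $\hat\tau = \max\!\big(10^{-8},\; \text{mean}_j\big[(r_j - 1)^2 -
   \hat\phi \sum_i \mu_{ij}^2 / E_j^2\big]\big)$ — the observed squared
   deviation of the ratios minus their sampling noise;
5. $\hat u_j = \dfrac{\hat\alpha + O_j/\hat\phi}{\hat\alpha +
   E_j/\hat\phi}$ with $\hat\alpha = 1/\hat\tau$, equivalently
   $w_j r_j + (1 - w_j)$ with reliability
   $w_j = \frac{E_j/\hat\phi}{E_j/\hat\phi + \hat\alpha}$,

iterated until the largest coefficient change falls below 1e-6 (50
iterations maximum; a non-converged fit is returned with
`converged = FALSE` and a warning). One numerical subtlety: the
alternation is only identified up to a constant split between the
intercept and the mean of $\hat u$; left alone, the mean of $\hat u$
drifts slowly while the intercept compensates and the iteration never
meets a tight tolerance. The offsets therefore use $\hat u$
renormalized to mean 1 each round (the mean-1 convention), while the
reported $\hat u_j$ is the raw step-5 value, which by construction lies
between 1 and $r_j$ — every estimate is a reliability-weighted
compromise between the region's raw observed/expected ratio and the
national norm. The $\tau$ floor of 1e-8 avoids division by zero in
$\hat\alpha$; an estimate at the floor is reported as no detectable
regional variation (`tau_at_floor`).

The reliability-adjusted mean cost for region $j$ is indirect
standardization of the shrunken ratio
(`compute_hrr_estimates()`):

$$\widehat{\text{mean}}_j = \hat u_j \times \frac{1}{N}\sum_{ij}
\mu_{ij},$$

the regional ratio scaled by the national average case-mix-predicted
cost. Shrinkage is toward the national mean (not a stratum mean), and
component models are fit separately per component with the same
covariates — both points where the design was open; separate fits match
the re-ranking structure of the reporting stage. "Price-standardized
only" estimates are the same pipeline with an intercept-only model, so
the adjusted and unadjusted rows differ only in the case-mix term.

## Quintiles and variation statistics

Regions are ranked ascending on the adjusted mean (ties broken by HRR
id), and rank $k$ of $J$ goes to the smallest quintile $q$ with
$k \le \lceil qJ/5 \rceil$ — quintile sizes differ by at most one.
Quintile averages are unweighted across member HRRs (the analysis unit
is the region; episode-weighted averages sit behind a flag), with 95%
percentile-bootstrap intervals (1000 seeded replicates by default; the
interval method was unspecified upstream, the bootstrap is this
package's choice). The variation statistics are

* absolute difference: Q5 mean − Q1 mean, whole dollars;
* percentage difference: 100 · (Q5 − Q1) / Q1, whole percent,

both rounded half away from zero. When a component's lowest quintile
mean is zero (readmissions often are), the percentage is flagged
undefined and the absolute difference still reported. Published
benchmark tables of this kind print differences computed *before*
rounding the quintile means, so recomputing from printed means can
disagree by $1; the worked-example fixture
(`inst/extdata/example_quintile_means.csv`) records which rows
reconcile exactly.

## The synthetic generator

`sim_config()` defaults describe the study conditions the pipeline is
meant for: 40 HRRs with 80–120 episodes each (~4,000 episodes, the
packaged end-to-end scale), five procedures in realistic volume shares,
per-procedure readmission probabilities of 6% (PHR), 6% (PKR), 13%
(CABG), 7% (LSF) and 20% (colectomy), a 20% dual-coverage rate, 0.5%
facility-source admissions and in-hospital deaths, wage indices uniform
on [0.85, 1.25], a component mix of 68/8/4/20 percent
(index/readmission/post-acute/professional), and a between-HRR effect
variance τ = 0.04. Episode totals are gamma with coefficient of
variation 0.9 around the model mean — cost data for a single elective
procedure are strongly right-skewed. Costs are split into components in
exact cents (conservation holds to $0.01 by construction), claims are
wage-inflated by the exact inverse of the standardizer, and designated
episodes carry each exclusion trigger plus an out-of-window claim at
day 91 as a boundary probe. All randomness flows from the single config
seed.

What the generator does **not** emulate — and hence what passing tests
do not establish about real data: realistic ICD/DRG code semantics,
actuarially calibrated price levels, calendar seasonality, transfers
between facilities, longitudinal correlation beyond one episode, and
claim adjudication artifacts (denials, adjustments, coordination of
benefits). Dates are integer day offsets from a fixed epoch; only day
arithmetic is ever used.

## Validation experiment sizes

Chosen once, as the package's own experiment design:

* **Parameter recovery** — 60 HRRs × 100 episodes, τ = 0.04, 20 seeds;
  recovery bands of ±0.05 per coefficient and [0.02, 0.07] for τ. The
  recovery runs use outcome CV 0.5 so the band corresponds to roughly
  3–5 standard errors per coefficient — at the generator's default CV
  0.9 the same band would be under-powered for the maximum error across
  nine coefficients, which would test sampling noise rather than the
  estimator. Noise-free recovery is exact (checked separately to 1e-6).
* **Confounding demonstration** — 30 HRRs × 60 episodes with a regional
  Charlson-mix shift of SD 1.0, 20 seeds: the case-mix-adjusted
  inter-quintile percentage is below the intercept-only percentage at
  the median, showing that the adjustment removes case-mix-driven
  regional variation. SD 1.0 makes the case-mix share of between-region
  variance (~a quarter) clearly visible; the direction, not the
  magnitude, is the claim.
* **Wage-only null** — 12 HRRs × 100 episodes, τ = 0, wage indices on
  [0.7, 1.4]: after standardization a one-way ANOVA of log cost on HRR
  is indistinguishable from the null (p > 0.05), while the raw amounts
  show the regional price signal at p < 0.001.
* **Rank fidelity** — 25 HRRs × 200 episodes, τ = 0.04: median Spearman
  correlation between estimated and true regional effects exceeds 0.8.

## Known limitations

* The estimation scheme is a moment/quasi-likelihood substitute for a
  full-likelihood gamma-frailty GLMM; τ̂ is slightly conservative in
  small regions (the sampling-noise subtraction can push it to the
  floor when regions have only a handful of cases — visible as full
  shrinkage for low-volume procedures).
* Reliability weights treat the dispersion as common across regions.
* Component models reuse the total-cost covariate specification; no
  component-specific selection is attempted.
* The zip→HRR crosswalk is consumed as given; one wage index per zip.
* With fewer than five regions quintiles are undefined and the
  reporting stage refuses to run.
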