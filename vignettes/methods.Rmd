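---
title: "Models and methods behind cylsfm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cylsfm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cylsfm)
```

cylsfm implements the analysis pipeline of the rotating-cylinder
structure-from-motion (SFM) bi-stable perception paradigm: stimulus
kinematics, a generative observer model for synthetic cohorts, behavioral
event scoring, and the group-level statistical battery. This vignette
explains each model, the tunable parameters and their defaults, the
numerical choices, and what the synthetic data do and do not establish.

## Stimulus kinematics

The stimulus is the classic dot-defined rotating cylinder: 400 small black
and white squares (0.25°, 200 of each polarity) inside a 7°-wide,
10°-tall aperture, split into two sheets of 200 dots that move in
counterphase — the front and back surfaces of the cylinder. The cylinder
construction fixes each dot's height and initial angle and projects
uniform circular motion onto the screen plane:

$$x(t) = R \sin(\omega t + \varphi_0), \qquad R = \tfrac{w}{2} = 3.5°,
\quad \omega = 90°/\mathrm{s},$$

so horizontal speed $R\,\omega\cos(\omega t + \varphi_0)$ is maximal at
the aperture midline and zero at the edges — the velocity profile that
makes a flat dot field look like a cylinder rotating in depth. The
projection formula itself is the standard SFM construction; it is the
unique smooth motion consistent with a rigid rotation at the labelled
speed. Sampling is at 60 Hz by default (a typical display rate),
configurable through `cylinder_params()`.

Two consequences are used as internal checks: a full period between
positive-going zero crossings is $360°/90°\mathrm{s}^{-1} = 4$ s, and an
edge-to-edge traversal (half rotation) takes 2 s. `fit_angular_speed()`
inverts the projection: it unwraps $\arcsin(x/R)$ (choosing the branch
from the sign of the sampled velocity, then closing $2\pi$ wraps) and
regresses phase on time, recovering the configured speed to numerical
precision on noiseless trajectories.

The real-switch control block overlays depth cues that disambiguate the
rotation and physically reverses it on a fixed timeline: 11 reversals in
120 s with inter-switch intervals drawn from {9, 11, 13} s. Eleven
intervals of mean 11 s would exceed the block, so random schedules are
rejection-sampled until all 11 switches fit; the first interval is drawn
from the same set (the design gives no reason to treat it differently). A
fixed canonical schedule (`seed = "paper"`, intervals
9, 11, 9, 13, 9, 11, 9, 13, 9, 11, 9) ships so that every simulated
subject can see the identical timeline, as in the task. Occlusion ordering
of crossing dots is not modelled: the package generates coordinate time
series for analysis, not rendered frames, and no analysis step depends on
which dot occludes which.

Dot heights are drawn once per stimulus; whether an experiment would
re-randomise them per block does not affect any downstream statistic here,
so the generator keeps them fixed for a given seed.

## The synthetic observer

No raw behavioral data ship with the package, so every downstream stage is
exercised against a generative observer whose *statistical structure*
matches what the analysis assumes. It is a stand-in, documented as such,
not a mechanistic model of rivalry circuits.

**Bi-stable blocks.** Percept dominance durations are a gamma renewal
process, the standard descriptive family for bi-stable alternation
statistics: durations $\sim \Gamma(k, \theta)$ with shape $k = 4$ by
default (empirical dominance-duration distributions are unimodal and
right-skewed with CV around 0.5, which gamma shape 3–5 reproduces) and
scale set by the subject's switch rate. The observer reports the initial
percept after a lognormal onset latency (mean 1.5 s) and thereafter
alternates at the renewal epochs, truncated at the 120-s block end.

**Real-switch blocks.** Each physical reversal is reported with
probability $1 - p_{\text{miss}}$ after a lognormal reaction time
(median 1 s, $\sigma_{\log} = 0.4$, so essentially all responses fall
inside the 4-s window), with the wrong direction with probability
$p_{\text{err}} = 0.02$; spontaneous illusory-reversal reports are a
superimposed Poisson process (0.01 Hz). Lapse rates vary across subjects
(Beta-distributed around the cohort mean, concentration
`miss_prob_kappa = 6`) so that the inclusion screen has realistic
heterogeneity to act on.

**Cohorts.** Switch rates are modelled on the log10 scale — the scale the
analysis itself uses. Per subject $i$ in group $g$ and session $s$:

$$\eta_{is} = \mu_g + b_i + \varepsilon_{is}, \qquad
b_i \sim N(0, \sigma_b^2), \quad \varepsilon_{is} \sim N(0, \sigma_e^2),$$

and each bi-stable block's gamma scale is
$\theta = 1 / (k \cdot 10^{\eta_{is}})$, so $10^{\eta_{is}}$ is the
subject's latent switch rate in Hz. The defaults place the control mean at
$\mu_c = -0.9$ (≈ 0.126 Hz, a typical bi-stable SFM alternation rate and
close to the physical 0.09 Hz of the control task), with a common
per-measurement SD of 0.25 log10 units. The PwPP mean sits
`target_d` = 0.58 pooled SDs above the controls — a medium effect, with
faster switching in the psychosis group — and the relatives' mean lies
halfway in between (`relative_position = 0.5`), reflecting the
intermediate pattern expected under a graded genetic-liability account.
The group-level separation, reliability and correlation defaults are
calibration constants chosen to mirror the effect sizes this paradigm
produces in three-group psychosis studies; the per-group means and SD of
log10 rates themselves are not published quantities, so they are labelled
approximate and are fully configurable.

**Reliability.** The variance split solves the ICC(3,k) identity for
$k = 2$ sessions,

$$\mathrm{ICC}(3,k) = \frac{k\sigma_b^2}{k\sigma_b^2 + \sigma_e^2},$$

under the constraint $\sigma_b^2 + \sigma_e^2 = 0.25^2$, so the default
target of 0.88 gives $\sigma_b^2 = 0.0491$, $\sigma_e^2 = 0.0134$.
Finite 120-s blocks add a small measurement variance on top of
$\sigma_e^2$ (about 0.0006 at these rates), which attenuates the
recovered ICC by under 0.01 — well inside the recovery tolerance, so the
generator does not attempt to pre-compensate for it.

**Covariates.** Clinical scores (BPRS, SPQ, BACS, SGI, BPRS-D, SPQ-CP)
and metabolite concentrations (GABA, glutamate, glutamine) are coupled to
the session-1 latent rate $\eta_{i1}$ through a Gaussian copula: the
latent Pearson correlation is $\rho_P = 2\sin(\pi\rho_S/6)$, the exact
inverse of the bivariate-normal Spearman identity, so each covariate hits
its Spearman target ($\rho_S = 0.264$ for the BPRS disorganization factor,
$-0.16$ for GABA, and analogous defaults for the rest). Covariates are
conditionally independent given the rate latent, which keeps the joint
correlation matrix positive-definite for any admissible set of targets.
The marginals are plausible instrument scales applied pooled across
groups; per-group marginal shifts are deliberately not added, because they
would compound with the group rate differences and move the pooled rank
correlations off their calibration targets. This is the one place the
synthetic cohort is *less* structured than real data.

**Determinism.** Everything derives from one master seed via fixed-label
sub-streams (subjects, bi-stable blocks, real-switch blocks). The
count-level path (`events = FALSE`) runs the same draws in the same order
and skips only event-table assembly, so its per-block switch counts are
bit-identical to scoring the event path — a property the test suite
asserts — which is what lets replicate-heavy studies (type-I error,
calibration recovery) run at scale honestly.

## Event scoring

A *switch* is a direction change in the reported stream. The initial
keypress reports the starting percept and is not a switch; repeated
same-direction keypresses report no new percept and are ignored. Percept
durations are the gaps between consecutive distinct reports, so they begin
only after the initial response; the final interval, cut off by the block
end rather than by a report, is flagged censored and excluded from
duration summaries because its length is truncation-biased. These rules
make the identity

$$t_{\text{first}} + \sum \text{durations} + \text{censored tail} = 120
\text{ s}$$

hold exactly for every block, which the suite checks verbatim.

Switch rate is count/120 s per block. Since a block can legally contain no
switches and $\log_{10} 0$ is undefined, zero counts are replaced by 0.5
switches per block *inside the log transform only*; the linear rate keeps
the true zero. Subject-level aggregation is the mean of per-block log10
rates (log-then-mean): the replacement rule is defined per block, so
applying the transform per block and averaging keeps one convention
throughout, and it is the natural scale on which the group differences are
modelled. The coefficient of variation is sd/mean of a subject's pooled
completed durations, per task type.

Real-switch scoring credits each physical reversal at most once, by the
earliest subsequent response that matches the post-switch direction with
latency strictly inside the 4-s window; responses are consumed once. With
eligibility windows that are intervals in time, this greedy earliest-match
rule attains the maximum possible number of credits — the suite checks it
against an exhaustive optimal-matching oracle on random instances,
including windows wide enough to overlap (impossible at the task's 9-s
minimum spacing, but enforced for generality). Correct-direction responses
arriving *before* their reversal are never credited: strict causality is
the only defensible rule when the design is silent. Inclusion requires at
least 7 of 11 credits; 7/11 = 63.6%, the printed boundary. Reaction-time
summaries are emitted both for credited responses and for the nearest
correct-direction response per reversal without the window cap, since a
window-capped mean is the conservative choice but both are defensible.

## The statistical battery

All group tests run on included session-1 data, one value per subject
(per-subject means rather than per-block values, because the group tests
assume independent observations; per-block rates feed only the
repeated-measures block analysis).

- **Kruskal–Wallis** (tie-corrected, χ² reference) for group differences
  in rate and in duration CV; pairwise post-hoc comparisons are the
  two-group KW (χ² with 1 df, identical to the squared tie-corrected
  rank-sum z), Bonferroni-corrected over the three pairs, with Cohen's
  *d* on log10 rates attached (pooled-SD formula; the sign follows the
  order of the pair's labels).
- **Kolmogorov–Smirnov** two-sample tests compare percept-duration
  distributions pooled across participants within group, per task type.
  The p value is asymptotic by design; pooled durations number in the
  thousands, where the asymptotic form is accurate. Both the pooled
  sample sizes and the contributing-subject counts are reported, because
  a pooled-duration KS has an effective n far larger than the subject
  count and readers should see both.
- **ICC(3,k)** — two-way mixed, consistency, average-measures,
  $(\mathrm{BMS} - \mathrm{EMS})/\mathrm{BMS}$ from the explicit
  sums-of-squares decomposition — for session-1 vs session-2 mean rates of
  subjects included in both sessions.
- **Exclusion contingency**: Pearson χ² (df = 2, no continuity
  correction) on the included/excluded × group table. If no subject is
  excluded the table is degenerate and the entry is skipped with a
  warning rather than fabricated.
- **Block effect**: one-way repeated-measures ANOVA (subject-stratified
  error) on per-block log10 rates. No sphericity correction by default;
  Greenhouse–Geisser ε (computed from the doubly-centred covariance of
  the subject × block matrix, clamped to $[1/(k-1), 1]$) is available as
  an option. In the fully degenerate case of zero within-subject
  variance the F ratio is 0/0; the function reports it as computed
  rather than inventing a value.
- **Spearman correlations** (tie-aware, t-approximation p) between
  session-1 mean rates and each clinical score, Bonferroni over the
  6-test clinical family; and between rates and each metabolite, pooled
  and per group, Bonferroni within the pooled family (3 tests) and
  within the per-group family.

Each wrapper delegates the standard computation to the corresponding base
R routine and is cross-checked in the suite against an independent
hand-coded oracle (rank formula, ECDF scan, direct $\sum (O-E)^2/E$,
ANOVA mean squares).

## Validation design and what it shows

The suite validates the pipeline at these problem sizes, chosen to give
each estimate comfortable Monte Carlo precision: renewal and CV properties
on 1200-s streams (10 block lengths); scorer-vs-oracle equivalence on 200
random instances; null type-I error of the group test on 2000 replicate
cohorts at the study-like group sizes 40/43/65 (rejection within
5% ± 1.5%); and calibration recovery on 100 replicate cohorts of 200 per
group (Cohen's *d* within ±0.15 of 0.58, ICC within ±0.05 of 0.88,
symptom and GABA Spearman ρ within ±0.05 of 0.264 and −0.16). The
replicate studies use the count-level generator path, whose exactness is
itself a tested property, not an approximation.

Passing these tests shows that the *pipeline* is correct and internally
calibrated: the scorer inverts the generator, the statistics match their
definitions, and effects put in come back out at the right size. It does
not show that real observers are gamma-renewal processes, that real
covariates are copula-coupled, or that the field's effect sizes are
reproduced from raw data — the printed group statistics of any particular
study depend on that study's data and are expressly not targets here.

## Known limitations

- The generative observer has no serial dependence between successive
  durations, no within-block adaptation (unless `block_log10_slope` is
  set), and no key-mapping errors in bi-stable blocks.
- Metabolite and clinical marginals are synthetic scales; only their rank
  coupling to switch rate is calibrated.
- The real-switch percept-duration distribution is schedule-dominated by
  construction, so group differences there arise only through lapse and
  spontaneous-reversal heterogeneity.
- KS p values are asymptotic; for very small pooled samples an exact
  variant would be preferable.
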