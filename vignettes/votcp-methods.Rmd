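---
title: "Scoring categorical perception of voicing and its cognitive correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring categorical perception of voicing and its cognitive correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(votcp)
```

## The problem

Voice onset time (VOT) — the lag between a plosive's release burst and the
onset of vocal-fold vibration — separates voiced from voiceless stops. In
French the /d/–/t/ phonemic boundary sits near 0 ms VOT, while universal
psychoacoustic ("allophonic") boundaries sit near −30 and +30 ms.
Categorical perception (CP) of this continuum is measured with two tasks
over a six-step grid (−75, −45, −15, +15, +45, +75 ms): *identification*
(label each token /d/ or /t/; 10 trials per step, 60 in all) and
same–different *discrimination* of adjacent one-step pairs (both orders of
the five different pairs plus the six identical pairs, five repetitions
each, 80 trials).

Children with developmental dyslexia often show a blunted CP profile, and
the theoretical question this toolkit is built around is whether that
deficit travels with *phoneme awareness* (PA: deletion, segmentation,
acronym blending) rather than with the *visual attention span* (VA span:
global and partial letter report), and whether the effect of CP on reading
accuracy is mediated by PA while VA span contributes to reading through an
independent route. `votcp` implements the full analysis chain — design
construction, per-child scoring, norm-referenced profiling and deficit
subtyping, group inference, and causal-steps mediation — together with a
synthetic cohort generator whose planted structure embodies those
hypotheses, so that every stage can be exercised and validated end to end.

## Scoring model

### Identification curve and phonemic boundary

Per child, `tabulate_identification()` turns trials into per-step /t/
proportions. `fit_boundary()` fits

$$P(\text{/t/} \mid \mathrm{VOT}) = \mathrm{logistic}\!\left(\frac{\mathrm{VOT} - \mu}{s}\right)$$

by penalized maximum likelihood, where $\mu$ (ms) is the 50% crossing —
the phonemic boundary — and $s$ (ms) the slope scale (smaller = sharper).
The likelihood carries Firth's Jeffreys-prior penalty. Two properties of
the design force this choice. First, near-step curves are common at 10
trials per step, and the unpenalized fit diverges under complete
separation. Second, the grid is sparse (six points, only two of them near
the boundary), and the plain MLE of $\mu$ is visibly biased away from the
grid center at realistic slopes: in simulation at $\mu = 10$, $s = 8$, the
unpenalized fit averages ≈ 11.9 ms whereas the Firth fit averages ≈ 9.8 ms.
The penalty is the standard bias-reduction device for exactly this
situation. A child who gives one label everywhere (or whose fitted slope
is non-positive) has no identifiable boundary; the fit is flagged
`converged = FALSE` and such children are dropped pairwise from
boundary-based correlations.

Note what penalization cannot buy: with 10 trials per step and $s = 8$ ms,
the Fisher information bounds the per-child standard error of $\mu$ at
roughly 4–5 ms, so individual boundaries are intrinsically noisy; the
estimator is accurate *on average* (group means recover the generative
boundary to well under 1 ms at n = 500), which is the level at which the
analyses use it.

### Observed and predicted discrimination

For the adjacent pair $(i, j)$, the observed hit rate pools "different"
responses over both presentation orders, and the false-alarm rate is the
mean of the "different" proportions on the two flanking identical pairs
$(i,i)$ and $(j,j)$ — both members of the pair contribute symmetric noise,
so neither identical pair is privileged. Sensitivity is the yes–no
signal-detection measure

$$d' = z(H^*) - z(F^*),$$

with the log-linear correction applied to *every* rate (add 0.5 to the
numerator count, 1 to the denominator), not only at 0 or 1. The uniform
correction keeps observed and predicted scores on one transform and keeps
$d'$ finite at ceiling (25/25 vs 0/25 gives $d' \approx 4.14$). A
differencing-model same–different $d'$ would also have been defensible;
the yes–no mapping is the simplest one consistent with a single response
criterion, and the generator uses the matching process model so the two
ends meet.

Predicted discrimination converts the identification curve into the
performance of an ideal *covert labeler*: two stimuli are judged
"different" exactly when they receive different covert labels, so

$$H_{\mathrm{pred}} = p_i(1-p_j) + p_j(1-p_i), \qquad
  F_{\mathrm{pred}} = \tfrac{1}{2}\left[2p_i(1-p_i) + 2p_j(1-p_j)\right],$$

with the same corrected $d'$ transform using the identification design's
trial counts as pseudo-counts. The package verifies $H$ and $F$ against
exhaustive enumeration of the four covert-label outcomes.

### Peaks

The discrimination peak is the pair with the largest $d'$; its amplitude
indexes boundary precision and its center tracks boundary location. Ties
are broken toward the smallest absolute center, then toward the negative
center — a deterministic rule that favors the phonemic (0 ms) region over
the allophonic flanks when the profile is flat. Group-level boundary
summaries use the bias-adjusted Fisher–Pearson skewness $G_1$.

## The synthetic cohort

`cohort_config()` / `simulate_cohort()` generate a study of 63 control and
63 dyslexic children (17 with an isolated PA-risk profile, 20 with an
isolated VA-span deficit, 26 others), with group-specific ages (months;
controls 121 ± 11, PA subgroup 130 ± 15.4, VA-span subgroup 120 ± 15.2,
clipped to 94–153).

Latent traits follow a linear Gaussian path model. Writing CP for the
standardized negated identification scale (sharper = better),

$$\mathrm{PA} = a\,\mathrm{CP} + e_1,\qquad
  \mathrm{ReadAcc} = b\,\mathrm{PA} + c'\,\mathrm{CP} + d\,\mathrm{VAS} + e_2,\qquad
  \mathrm{ReadSpeed} = d_s\,\mathrm{VAS} + e_3.$$

Reading speed deliberately loads on VA span and not on PA: the double
dissociation and the mediation route CP → PA → reading accuracy, with an
independent VAS → reading path, are the planted hypotheses. Defaults:
$a = b = 0.4$, $c' = 0.1$, $d = 0.35$, $d_s = 0.45$; disturbance SDs 0.6.
The disturbance scale was fixed once by design-time power analysis: it
makes the trait-level CP–PA correlation ≈ 0.5 and leaves the *measured*
(task-level) correlations near the magnitudes this literature typically
reports once task noise is added. Task scores are affine in the traits on
each task's printed scale
(`score = norm mean + norm SD × (trait + task noise)`, clipped to range);
task-noise SDs (0.8 for PA tasks, 0.82 for report, 0.6 for reading
accuracy, 0.55 for times, in norm-SD units) were chosen to reproduce
typical inter-task correlation ranges (PA tasks 0.33–0.43, report tasks
≈ 0.60, reading accuracy 0.33–0.67, times 0.64–0.83). Note that tasks whose
norm mean sits about 1 SD below ceiling (e.g. deletion) lose ≈ 1 point of
mean to range clipping — a feature of bounded scales, not a bug.

The psychophysics layer responds per trial. Identification is Bernoulli
with the logistic labeling probability. Discrimination is yes–no SDT on
the true pair discriminability

$$d_{\mathrm{true}}(i,j) = d_{\max}\,\lvert p_i - p_j\rvert
  + w_a\!\left[e^{-(c_{ij}+30)^2/2w^2} + e^{-(c_{ij}-30)^2/2w^2}\right],
  \qquad P(\text{"different"}) = \Phi\!\left(d_{\mathrm{true}}/\sqrt{2} - c\right),$$

with $c_{ij}$ the pair center. The allophonic bumps sit at ±30 ms with
width 10 ms; their default weight is **0**, because behavioral allophonic
sensitivity is typically absent in ten-year-olds (it is inhibited with
school experience), and the default cohort emulates that age group. The
weight is a config knob for younger or unremediated profiles. Defaults
$d_{\max} = 3.5$ and criterion $c = 0.5$ give identical-pair false-alarm
rates ≈ 0.3 and mid-continuum hit rates well off ceiling, which is where
children in this paradigm live.

The PA deficit is implanted *upstream*, as a +6 ms worsening of the
identification scale in the PA subgroup (their PA scores then fall through
the $a$ path), while the VA-span deficit is a −1.8 SD shift of the VAS
trait with the perceptual layer untouched. This is the strong reading of
the dissociation hypothesis and is what makes the subgroup contrasts
behave the way the group analyses expect.

What the generator does **not** emulate: item-level linguistic content of
the PA tasks, grade-stratified norms (one norm stratum per cohort; ages
enter only as a covariate), reading development over time, response times
in the psychophysics tasks, lapses/attention drift, and any dependence of
trait noise on age. Passing tests therefore show that the pipeline
recovers what was planted under a clean measurement model — not that real
child data are this well behaved.

## Group inference

The headline analysis is a mixed repeated-measures ANOVA on $d'$ with
Group between subjects and Task (observed vs predicted) × VOT pair center
(−30, 0, +30 ms) within. Sums of squares come from `stats::aov` error
strata; the Greenhouse–Geisser epsilon of every within effect is computed
from the pooled within-group covariance of the participant × cell matrix
and applied to the F degrees of freedom of every effect involving that
within factor, regardless of any sphericity pretest — uniform correction
is the reporting convention the package mirrors. Effects with one
numerator df have epsilon exactly 1. Effect sizes are *partial*
eta-squared, $\mathrm{SS_e}/(\mathrm{SS_e} + \mathrm{SS_{err}})$, and are
labeled as such (the classical/partial distinction is ambiguous in much
applied reporting; partial is the one consistent with
$F \cdot df_1 / (F \cdot df_1 + df_2)$).

Peak analyses use an ANCOVA `amplitude ~ Group + Location +
Group:Location` with Type-II tests (via `car::Anova`), so the Group effect
is read adjusted for peak location. Correlation structure is summarized by
age-partialled Pearson correlations (residualize both variables on age;
t-test on n − 3 df), with pairwise deletion for children without a
convergent boundary fit.

`age_match_controls()` reproduces the subgroup age-matching procedure:
iteratively drop the single youngest control (ties broken by identifier)
until the one-way ANOVA on age is non-significant at alpha = 0.10. Such
matching is usually reported only by its outcome (the anchor case for this
package: 15 youngest controls removed, final p = .122); one-at-a-time
removal with a 0.10 stop rule is the simplest procedure compatible with
it, and on synthetic ages carrying the anchor moments (130 ± 15.4 vs
121 ± 11, n = 17/63) it removes 14 and stops at p ≈ .11.

## Mediation

`causal_steps()` runs the three ordinary-least-squares models, with age in
all of them and VA span as an additional regressor on reading:

1. PA ~ age + CP (path *a*);
2. ReadAcc ~ age + CP + VAS (total effect *c*, path *d*);
3. ReadAcc ~ age + CP + PA + VAS (direct effect *c′*, path *b*, *d′*).

Mediation is claimed when *a*, *c* and *b* are significant (two-sided
alpha = .05) and *c′* is not. The indirect effect $ab$ is tested with the
Sobel statistic $z = ab/\sqrt{b^2\sigma_a^2 + a^2\sigma_b^2}$, reported
with a **one-sided** p-value ($1 - \Phi(z)$): the hypothesis is
directional (better CP → better PA → better reading), and the one-sided
tail is the convention this package adopts (z = 1.40 pairs with p = .081;
the two-sided value would be .162). The CP index entering the
model — the predicted-peak amplitude — is chosen by an explicit, logged
scan (`scan_cp_candidates()`) over candidate CP indices' age-partialled
relations with PA, making the exploratory selection step visible instead
of implicit. The exact decomposition $c = c' + ab$ holds when all three
models share one regressor set; the classical model set omits VAS from
model 1, so the identity is approximate there (`vas_in_model1 = TRUE`
restores it, and the test suite asserts it to 1e−8).

## Numerical and procedural choices

* Randomization everywhere is R's Mersenne–Twister under an explicit
  integer seed (default 0), isolated from the caller's RNG state; per-child
  streams are derived deterministically from the master seed, so a cohort
  is a pure function of its config and runs are byte-reproducible.
* Letter-report stimulus sets (20×5 global, 50×5 partial over 10
  consonants) are built by column-balanced quota sampling with restart on
  dead ends: per-position letter quotas, no within-string repeats, and a
  configurable forbidden-bigram blocklist (default PH, TH, TR, PL, BR and
  reverses — French graphemes and frequent bigrams; full real-word
  skeleton screening would need a lexicon). Partial-report cues are
  assigned by bipartite matching so each trial carries one cue and every
  letter × position combination is cued exactly once. Invariants are
  re-counted post hoc by an independent routine rather than trusted from
  the construction.
* The discrimination design uses the six identical pairs of the grid: with
  five adjacent pairs in both orders at five repetitions, 80 trials decompose
  as 30 identical + 50 different, which fixes the identical-pair count at six.
* Degenerate inputs are signalled, not patched: non-identifiable
  boundaries via `converged = FALSE`, constant ANOVA responses via a
  `degenerate` attribute, unmatched age distributions and rank-deficient
  mediation designs via errors with diagnostics.
* GG-corrected p-values can fall marginally below uncorrected ones when
  F < 1 (a property of rescaling both df of an F tail); the monotonicity
  guarantee applies to effects with F ≥ 1.

## Problem sizes used by the test suite

The validation suite runs at sizes chosen to make the statistical checks
sharp while staying desk-scale: 500 simulated identification curves for
boundary recovery; 200 cohort replicates (n = 126) for planted-mediation
detection; 1000 null replicates for Sobel type-I calibration; 20 seeds of
the full default study (n = 126, 140 trials/child) for the qualitative
sign-pattern check; 10^6 Monte-Carlo draws for the covert-labeling oracle;
300 repetitions per pair where the observed-d′ monotonicity invariant
needs binomial noise suppressed.

## Known limitations

* The yes–no SDT mapping for same–different data is a modeling choice; a
  differencing-model observer would yield systematically different d′
  magnitudes (not orderings) at equal true discriminability.
* Individual boundary estimates are information-limited (see above);
  analyses that correlate individual boundaries inherit that noise.
* Norms are synthetic stand-ins on the tasks' printed scales; Z-scores
  against them are internally consistent but not clinically referenced.
* The no-deficit and double-deficit subgroups are labeled but not used in
  subgroup CP contrasts; they are heterogeneous by construction.
* The causal-steps + Sobel approach is the classical procedure; it is
  known to be conservative and is not supplemented by bootstrap indirect
  intervals here, because the point is fidelity to the original analysis
  chain.

## A worked run

```{r, eval = FALSE}
cfg <- cohort_config(seed = 1)
res <- run_study(cfg, out_dir = "votcp_demo")
format_anova(res$anova)
res$mediation
```

See the README for the outputs this prints and how to reproduce the
acceptance quantities with `scripts/acceptance.R`.
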