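---
title: "Retrieval dependency and cortical reinstatement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieval dependency and cortical reinstatement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopdep)
```

# The scientific problem

Episodic memories bind several elements — a place, a person, an object —
into one representation, and recalling any one element can bring back the
others ("holistic recollection", attributed to hippocampal pattern
completion). `loopdep` implements the behavioural and statistical machinery
of a paradigm that probes this: participants learn 36 multi-element events
as pairwise associations, where half of the events form *closed loops*
(three elements, associations AB–BC–CA, fully overlapping) and half form
*open loops* (four elements, a chain AB–BC–CD). If closed-loop encoding
creates a coherent event representation, then success at retrieving one
association should predict success at retrieving the *other* associations
of the same event — retrieval dependency — and retrieving one pair should
incidentally reactivate cortical representations of the event element that
is neither cue nor target (nontarget reinstatement).

The package covers five stages:

1. **Design generation** — events, encoding schedule, bidirectional
   four-alternative forced-choice (4AFC) retrieval schedule.
2. **Cohort simulation** — behavioural outcomes and participant-level
   neural quantities with the statistical structure the analyses assume.
3. **Dependency analysis** — contingency tables, observed dependency, and
   independent/dependent model expectations, in accuracy and
   high-confidence scoring modes.
4. **First-level GLM** — boxcar-by-HRF regressors, nuisance/outlier
   columns, OLS fits and category contrasts; ART-style scan-outlier
   detection.
5. **Group statistics** — reinstatement scoring from ROI parameter
   estimates, repeated-measures ANOVA, one-sample loop-difference tests,
   subfield brain–behaviour correlations and dependent-correlation z-tests,
   voxelwise covariate maps with face-connected cluster extraction, and the
   anterior/posterior mask split.

# The experimental design

`build_event_set()` creates 18 closed-loop events (two 9-event sub-pools:
location–object–people and location–animal–people) and 18 open-loop events
(one element from each of location, object, animal, people). Object and
animal are merged into a single "object" analysis category; the fine
category is kept because the third encoding block must pair location or
people with an object/animal element. Encoding (`build_encoding_schedule()`)
presents one pair per event per block over three blocks; within an event,
consecutive blocks share exactly one element, which forces the middle chain
pair of an open-loop event into block 2. Retrieval
(`build_retrieval_schedule()`) tests each association twice, once per
direction, one trial per event per block over six blocks — 216 trials.
Lures share the target's merged category and come from other events.

Design choices worth stating:

* The six directed trials of an event are placed into blocks by free random
  permutation; the design constraint is only "one trial per event per
  block" plus exact bidirectional coverage.
* Onsets sit on a deterministic grid (duration + 1.5 s ISI + 0.5 s
  fixation) because the package's synthetic data have no response-dependent
  timing.
* Six retrieval trials per event times 36 events gives 216 trials; the
  per-event rule is structurally forced by bidirectional coverage of three
  associations.
* Every participant can receive an independently seeded event set
  (`shared_event_set = FALSE`); the default reuses one set, which is the
  more common fixed-materials situation and is cheaper to simulate.

# The generative model

`simulate_behavior()` uses a latent-trace Bernoulli mixture rather than a
continuous memory-strength model, because it makes the direction of every
downstream effect analytically forced and therefore testable:

* For each **closed-loop** event, a single holistic trace forms with
  probability `p_trace_closed`. All six retrieval trials of the event are
  governed by that one trace, which induces dependency across the event's
  associations.
* For each **open-loop** association, an independent trace forms with
  probability `p_trace_pair`; outcomes on different associations of the
  same event are independent by construction, so open loops carry no
  cross-association dependency.
* A trial governed by an existing trace is correct with probability
  `p_hit_given_trace`; otherwise the participant guesses (`g = 0.25`).
  Confidence is high (3–4) with probability `p_highconf_trace` under a
  trace and `p_highconf_guess` otherwise.
* `closed_pairwise = TRUE` switches closed-loop events to per-association
  traces. This is the *independence generator* used for null calibration:
  the closed/open contrast vanishes exactly.

Accuracy defaults follow `p * p_hit + (1 - p) * g` and were fixed once to
place the cohort in the high-performance regime typical of this paradigm:
`p_trace_closed = 0.89`, `p_trace_pair = 0.86`, `p_hit_given_trace = 0.96`
give closed ≈ 88.5%, open ≈ 86.3%, overall ≈ 87.4%. Response times are
truncated log-normal and exist only for format fidelity; nothing analyses
them.

## Neural coupling

`simulate_neural()` gives each participant a latent nontarget-reinstatement
score

\[ s = \alpha \cdot \widehat{f} + \varepsilon_s, \qquad
   \varepsilon_s \sim N(0, \sigma_s^2), \]

where \(\widehat{f}\) is the participant's realized holistic-trace fraction
over closed-loop events. Subfield closed−open activity differences are
\( \beta_{CA3}\, s + \varepsilon \) and \( \beta_{DG}\, s + \varepsilon \)
with noise scale `sigma_neural`. ROI condition estimates (6 ordered
category pairs × closed/open) have mean activity `mu_target` (1.0) when the
ROI's category is the target, `mu_cue` (0.6) when it is the cue and
`mu_nontarget` (−1.0) when it is absent, with the closed-loop nontarget
cells elevated by \( s \) and i.i.d. noise `sigma_beta` on every cell.

The default couplings were derived by propagating variances through the
scoring pipeline (z-scoring within participant × ROI across the 12 cells,
averaging 4 cells per function per ROI, then 3 ROIs): with
`alpha_reinstate = 1`, `sigma_score = 0.12`, `sigma_beta = 0.25`,
`sigma_neural = 0.2`, `beta_ca3 = 1`, `beta_dg = 0.4`, the population
correlation between a subfield difference and the *measured* nontarget
score comes out near 0.4 for CA3 and 0.2 for DG (R² ≈ 0.16 / 0.04) — the
moderate effect sizes such cohort analyses report. The z-scoring step
attenuates all couplings (the divisor is dominated by the fixed
element-function means plus cell noise), which is why the raw slopes look
large relative to the target correlations.

`preset_strong_holistic()` is a separate, deliberately exaggerated
configuration (traces on 60% of events, accuracy 0.9 under a trace,
`beta_ca3 = 1` vs `beta_dg = 0.15` at `sigma_neural = 0.2`) used for power
and parameter-recovery checks where near-certain detection at n = 30 is the
point.

## What the generator does *not* emulate

* fMRI noise structure: `simulate_bold()` produces white Gaussian noise
  only — no autocorrelation, drift or physiological artifacts — so the GLM
  path is tested for algebraic correctness, not robustness to coloured
  noise (and correspondingly no prewhitening is implemented).
* Participant heterogeneity in element-function amplitudes: `mu_cue`,
  `mu_target`, `mu_nontarget` are fixed across participants, so the
  element-function ANOVA F on synthetic cohorts is far larger than in real
  cohorts, where per-participant amplitude variation inflates the error
  term. The ANOVA's calibration (type-I error under a null generator) is
  what the tests establish.
* Item effects, fatigue, serial-position effects, and non-responses
  (simulated participants always answer within the deadline).

Passing tests therefore demonstrate that the *analysis code* recovers the
structure the generator injects — not that real data contain that
structure.

# Dependency analysis

For a participant and loop condition, every element that anchors two
retrieval trials of the same event in the same role (cue or target)
contributes one paired outcome; pairs are grouped into contingency tables
by (anchor category, role). Closed-loop events give the six canonical
tables (3 merged categories × cue/target, 18 events each). Open-loop events
qualify only through their two middle chain elements, and their tables are
keyed by *fine* category: an open-loop event contains both an object and an
animal element, so merged-category keys could place two pairs from one
event in the same table, which the table invariant (at most one pair per
event) forbids.

With outcomes \(o_{1i}, o_{2i}\) for event \(i\) and \(N\) events:

* **Observed dependency**: \( D_{obs} = (n_{11} + n_{00}) / N \).
* **Independent model**: \( D_{ind} = P_1 P_2 + (1-P_1)(1-P_2) \) with
  \(P_t\) the table's marginal success rates.
* **Dependent model**: guessing-corrected strengths
  \( m_i = \max(0, (A_i - g)/(1-g)) \) from per-event accuracy \(A_i\) (all
  six retrieval trials of the event by default;
  `episodic_factor_source = "exclude_table_trials"` removes the table's own
  two trials first), \( \bar m \) likewise from the grand mean over the
  loop condition's events, episodic factor \( E_i = m_i / \bar m \)
  (\(E_i = 1\) when \(\bar m = 0\)), per-trial-type predictions
  \( p_{t,i} = g + (1-g)\min\{1, E_i \max(0, (P_t-g)/(1-g))\} \), and
  \( D_{dep} = \frac{1}{N}\sum_i [p_{1,i} p_{2,i} + (1-p_{1,i})(1-p_{2,i})] \).

When all \(E_i = 1\) and the marginals are at or above chance, the
dependent model reduces exactly to the independent model; the test suite
asserts this to machine precision and checks the general case against a
brute-force per-event enumeration. The *evidence for dependency* is
\( D_{obs} - D_{ind} \), compared between loop conditions with paired
t-tests; because \(D_{obs}\) scales with accuracy, only such model-relative
comparisons are interpretable, and near ceiling accuracy the evidence is
compressed toward zero (visible in the confidence-scoring mode, which
de-saturates high-accuracy cohorts by counting only high-confidence correct
trials as successes). Non-response trials count as failures in both
scoring modes.

Numerical conventions: pairs are ordered chronologically (by block); an
all-zero difference vector in a paired test returns t = 0, p = 1, while a
constant nonzero difference is flagged degenerate with p omitted.

# First-level GLM

`canonical_hrf()` is the conventional double-gamma (peak 6 s, undershoot
16 s, dispersions 1, ratio 6:1, 32 s, unit peak). Condition regressors are
boxcars on a 0.1 s grid convolved with the kernel and sampled at scan
onsets; nuisance columns are an ISI regressor, six motion parameters and
one unit indicator per flagged scan, plus an intercept. Fits are OLS
(QR; eigenvalue pseudo-inverse with a warning if the design is rank
deficient), and contrasts return \( t = c'\hat\beta / \sqrt{\hat\sigma^2
c'(X'X)^{-}c} \). Including an outlier indicator column reproduces the fit
with that scan deleted — asserted numerically in the tests.

Scan outliers follow the ART conventions reduced to what is computable
from a motion trace and a global-signal series: frame-to-frame
displacement is the maximum over the six parameters of the absolute
between-scan difference (rotations converted at a 65 mm radius, the usual
head-radius convention), flagged above 2 mm; the global signal is flagged
beyond |z| = 9 (z-score units — the conventional reading of that
threshold). Participants are excluded when the flagged fraction strictly
exceeds 10%; exactly 10% is kept.

# Reinstatement scoring and group statistics

Parameter estimates are z-standardized within participant × ROI across
condition estimates, using the sample (n−1) SD convention — visible in a
two-condition cell, which standardizes to ±0.707. For the ROI mapped to
category X (defaults: parahippocampal cortex → location, medial parietal
cortex → people, lateral occipital cortex → object), conditions with X
first are cue conditions, X second target conditions, and X absent
nontarget conditions; scores average conditions within ROI, then ROIs. For
balanced tables this nesting equals a flat mean (asserted as a property).
With loop-split tables (14 regressors: 6 pairs × 2 loops + ISI + intercept)
the same scoring runs per loop, and closed−open differences per element
function are tested against zero with one-sample t-tests.

The element-function ANOVA is provided in two modes because the two are
genuinely different models with different error terms: `"repeated"`
(participant as blocking factor, df = (2, 2(n−1))) and `"oneway"`
(independent groups, df = (2, 3n−3)). Neither is endorsed; the repeated
version is the default as it matches the within-participant design.

Brain–behaviour statistics: Pearson correlation with the t-distribution
p-value; the Meng–Rosenthal–Rubin z for comparing two correlations sharing
one variable (appropriate for both reported uses — two reinstatement types
against shared cluster activity, and two subfields against shared
reinstatement); a voxelwise covariate correlation map thresholded at an
uncorrected cluster-defining p (default 0.005, one-sided positive since the
search is directional) with face-connected components and an optional
extent threshold `k_min` — mask-restricted uncorrected thresholding stands
in for small-volume familywise correction, which is out of scope. The
anterior/posterior mask split cuts at half the mask's extent along the
longitudinal axis, assigning the boundary slice to the posterior part (a
fixed tie-break for determinism).

# Problem sizes and tolerances used in validation

The shipped checks run at desk scale, chosen so each check has clear
resolving power: null calibration uses 500 simulated participants for
dependency evidence (tolerance |mean| < 0.01), 200 for the guessing floor
(0.25 ± 0.01), 5000 replicates for the z-test size ([0.035, 0.065] at
α = 0.05) and 2000 for ANOVA type-I error (0.05 ± 0.01); parameter
recovery uses 200 replicates of 30-participant cohorts under the strong
preset (≥95% detection of closed-loop evidence, ≥90% of the nontarget
loop difference, cue/target replicate-mean magnitudes below 10% of the
nontarget effect); exact checks (design counts, model reductions, GLM
recovery) use tolerances at machine precision or 1e−8.

# Known limitations

* The dependent-model algebra is reconstructed from its verbal
  description; published variants that differ in where the guessing
  correction enters would change \(D_{dep}\) slightly (the observed and
  independent-model quantities are unaffected).
* No autocorrelation modelling in the GLM; white-noise simulations only.
* Univariate reinstatement only; no multivariate pattern similarity.
* Cluster inference is uncorrected thresholding with extent filtering, not
  random-field or permutation inference.
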