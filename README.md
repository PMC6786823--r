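# loopdep

Retrieval-dependency and cortical-reinstatement analysis for multi-element
event memory experiments, with a fully synthetic cohort simulator.

## The problem

In multi-element event paradigms, participants learn events whose elements
(a location, a person, an object) are encoded as overlapping pairwise
associations. Events encoded as a fully overlapping cycle — *closed loops*,
AB–BC–CA — are thought to support **holistic recollection** via hippocampal
pattern completion: cueing one association incidentally reactivates the
event's other elements. Events encoded as a chain — *open loops*,
AB–BC–CD — serve as the control. `loopdep` is for researchers who analyse
(or simulate and power-check) this paradigm; it implements:

- **Design generation** — 36 events (18 closed / 18 open), a 3-block
  pairwise encoding schedule (108 trials) with category constraints, and a
  6-block bidirectional 4AFC retrieval schedule (216 trials) with
  same-category lures.
- **Retrieval dependency** — per-participant contingency tables pairing
  retrieval trials that share a cue or target element across associations
  of the same event. Observed dependency is the concordant-event proportion
  `(n11 + n00)/N`; it is compared against an **independent model**,
  `P1·P2 + (1−P1)(1−P2)`, and a guessing-corrected **dependent model** that
  weights each event by an episodic factor
  `E_i = m_i/m̄`, `m_i = max(0, (A_i − g)/(1 − g))`, predicting per-trial
  success `g + (1−g)·min(1, E_i·max(0, (P_t − g)/(1 − g)))` (4AFC chance
  `g = 0.25`). Both accuracy and high-confidence (ratings 3–4) scoring
  modes are supported; the *evidence for dependency* is `D_obs − D_ind`.
- **First-level GLM** — canonical double-gamma HRF, boxcar convolution,
  motion/ISI/outlier regressors, OLS fits, category contrasts, ART-style
  scan-outlier detection (2 mm displacement, |z| > 9 global signal, >10%
  participant exclusion).
- **Reinstatement scoring** — z-standardized ROI parameter estimates
  mapped to cue / target / nontarget element functions, overall and split
  by loop condition, with repeated-measures ANOVA and one-sample tests of
  closed−open differences.
- **Brain–behaviour statistics** — Pearson correlations of hippocampal
  subfield (CA3, DG) closed−open activity with nontarget reinstatement,
  Meng–Rosenthal–Rubin one-tailed z-tests comparing dependent
  correlations, voxelwise covariate maps with face-connected cluster
  extraction, and anterior/posterior mask splitting.
- **Synthetic cohorts** — a latent-trace Bernoulli generator
  (`simulate_cohort()`, `simulate_neural()`, `simulate_bold()`) whose
  closed-loop events share one holistic trace per event while open-loop
  associations are independent, so every downstream effect has a known
  sign and magnitude.

## Worked example

```r
library(loopdep)
res <- run_pipeline(pipeline_config(seed = 1))
#> simulate: 30 participants, 6480 trials
#> dependency (accuracy): mean closed evidence 0.0885, open 0.0002
#> dependency (confidence): mean closed evidence 0.1109, open -0.0151
#> reinstatement: mean nontarget closed-open diff 1.171
#> brain-behavior: R2 CA3 0.072, DG 0.019, z(CA3>DG) 1.544
```

The simulated cohort retrieves ~87% of trials correctly with closed-loop
accuracy slightly above open-loop. Dependency evidence (`D_obs − D_ind`)
is positive for closed loops only — the signature of holistic
recollection — and the paired test between loop conditions confirms it:

```r
res$dependency$confidence$tests[1, c("comparison", "t", "df", "p")]
#>                  comparison    t df        p
#> 1  evidence: closed vs open 9.88 29 8.67e-11
```

Only the *nontarget* element function shows a closed−open reinstatement
difference (cue and target sit at zero), i.e. incidental elements are
reactivated more after closed-loop encoding:

```r
res$reinstatement$loop_tests
#>   element_function   mean      t df        p
#> 1              cue 0.0254  0.876 29 3.88e-01
#> 2           target 0.0332  0.928 29 3.61e-01
#> 3        nontarget 1.1714 23.143 29 3.03e-20
```

Finally, the CA3 closed−open activity difference tracks nontarget
reinstatement across participants more than DG does, compared with a
one-tailed dependent-correlation z-test:

```r
res$brain_behavior$z_ca3_vs_dg
#> <loopdep_corcomp> r_j1=0.268 r_j2=-0.138 r_12=0.053 n=30 z=1.544 p(one-tailed)=0.0613
```

(All quantities are stochastic at n = 30; rerun with another seed for a
different cohort.) `run_pipeline(..., outdir = "out/")` additionally
writes the trial table (TSV), per-stage CSVs and a `summary.json`, all
byte-identical under a fixed seed. A thin command-line wrapper lives at
`inst/scripts/loopdep-run.R`.

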