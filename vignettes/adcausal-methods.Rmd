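---
title: "Methods: models, calibration and design choices in adcausal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibration and design choices in adcausal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`adcausal` benchmarks three structure-search strategies — constraint-based
(FCI), score-based (greedy equivalence search, GES/FGES) and SEM stepwise
edge addition — against a literature-derived gold-standard causal graph of
the Alzheimer's biomarker cascade, on synthetic cohorts whose marginals are
calibrated to a published cohort table. This vignette records the models,
the tunable parameters, and the design decisions made where the design was
genuinely open.

## The gold-standard graph

The cross-sectional graph has 8 nodes and 8 directed edges: `AGE→ABETA`,
`APOE4→ABETA`, `ABETA→PTAU`, `ABETA→FDG`, `PTAU→FDG`, `PTAU→DX`, `FDG→DX`,
`EDU→DX`, with `SEX` isolated. Seven of these follow unambiguously from the
amyloid-cascade literature summarized by the benchmark's source; the eighth
is our reading of "tangle formation and subsequently neurodegeneration" as
tau pathology preceding metabolic decline, hence `PTAU→FDG`. The edge set
is a plain data constant (`gold_edge_table()`), so users who read the
cascade differently can substitute their own 8-edge table.

The longitudinal graph duplicates `{ABETA, PTAU, FDG, DX}` into `.0` and
`.24` copies, repeats the within-visit structure at both visits, adds an
autoregressive edge `X.0 → X.24` per duplicated variable, and attaches
demographics to baseline targets only. This encodes the observation that
demographics act on the baseline assessment but not directly on the
24-month assessment once baseline is adjusted for. Lagged cross-edges such
as `PTAU.0 → DX.24` are plausible but are *excluded* from the default gold
standard: they were advanced as a hypothesis, not established knowledge.

## Background knowledge

Three levels, honored by all three search arms:

1. none — nothing prohibited;
2. trivial — every directed edge whose *target* is a demographic variable
   (`AGE`, `SEX`, `EDU`, `APOE4`) is prohibited, whatever its source
   (demographics may still be associated; in the FCI arm a
   demographic–demographic edge can surface as a bidirected edge, which is
   exactly "association without causation");
3. longitudinal — level 2 plus temporal tiers (demographics 0, baseline 1,
   month-24 2); only strictly backward-in-time edges are forbidden,
   within-tier edges are unconstrained.

Knowledge enters the searches twice: as move filtering (GES inserts and SEM
additions whose direction is forbidden are never proposed) and as endpoint
orientation (an adjacency whose one direction is forbidden is oriented the
other way, Tetrad-style: a forbidden `X→D` places an arrowhead at `X`, and
in the PAG arm arrowheads into `D` are disallowed).

## The cohort simulator

The generator is a linear-Gaussian structural equation model on the gold
DAG with a thresholded latent diagnosis. This is a deliberate choice: the
benchmark's statistical kernels (Fisher-z tests, Gaussian BIC) *assume*
linear-Gaussian data, so the generator makes faithfulness controllable and
lets every failure be attributed to the search, not to model mismatch.

Exogenous marginals are taken directly from the published cohort table:
AGE ~ N(74.09, 7.46²) years, EDU ~ N(16.15, 2.71²) years, SEX ~
Bernoulli(0.55), APOE4 categorical with P(0,1,2 alleles) = (0.54, 0.36,
0.10), treated as a numeric 0/1/2 column. Endogenous targets: ABETA 986.29
(459.94), PTAU 27.67 (14.76), FDG 1.22 (0.17); the latent DX\* is
standardized to mean 0, SD 1.

Effect sizes are specified on the standardized scale (child-SD change per
parent SD) and default to moderate values with biologically fixed signs
(lower ABETA → more tau, less metabolism, worse diagnosis): ABETA: AGE
−0.35, APOE4 −0.45; PTAU: ABETA −0.55; FDG: ABETA +0.30, PTAU −0.45; DX\*:
PTAU +0.35, FDG −0.40, EDU −0.20. These give each endogenous node an R² of
0.30–0.49, inside the 0.2–0.6 band the benchmark calls for. Raw
coefficients, intercepts and noise scales are then solved in closed form by
propagating means and covariances through the DAG in topological order; a
requested child SD smaller than the implied parent contribution raises an
"infeasible calibration" error rather than being silently clipped.

Diagnosis coding: conditional on APOE4 every variable is exactly Gaussian,
so the latent DX\* is a three-component Gaussian mixture whose CDF we can
evaluate exactly; the two thresholds are solved on that CDF so that the
coded CN/MCI/AD mix hits 31/46/23 % in population. Search algorithms
consume the *coded* 0/1/2 diagnosis (the simplest reading of how the
original analyses were run); the latent column is kept in the cohort for
diagnostics but dropped from covariance models.

Longitudinal defaults: autoregressive standardized weight 0.7 for each
duplicated variable, and within-visit weights at month 24 scaled by 0.5 so
the total explained variance stays below 1 once the autoregressive parent
is added. Two-year biomarker stability around 0.7 and somewhat attenuated
within-visit cross-sectional structure is what a cohort scientist would
call realistic for this design; the values are stated once here and are
configurable but not revisited.

What the generator does *not* emulate: missingness and record removal,
cohort-phase effects, non-Gaussian biomarker distributions (real FDG and
ABETA are skewed and often floor/ceiling-limited), genuinely ordinal
modelling of APOE4 and DX inside the tests, and selection bias. A green
test therefore establishes that a search algorithm behaves correctly on
faithful linear-Gaussian data of the published dimensions — not that it
would achieve the same metrics on the access-controlled clinical data.

## Statistical kernels

- Fisher-z: partial correlation `r` from the inverse covariance submatrix,
  `z = atanh(r)·√(n−|S|−3)`, two-sided normal p-value; `|r|` is clamped at
  `1 − 1e−12` before `atanh`. Default `alpha = 0.05` (the original analyses
  do not report theirs).
- BIC: `−n·ln σ̂² − c·(|parents|+1)·ln n` per equation, summed over nodes;
  penalty discount `c = 1` by default and exposed as a flag (also
  unreported in the source analyses). Higher is better. The same formula is
  used by GES, by the SEM arm and by `graph_bic_score()`, so "both arms
  optimize one criterion" holds exactly (verified to 1e−10 in the tests).

## Search arms

**GES.** Serial implementation (the "F" in FGES is parallelization, which
is irrelevant at ≤ 12 nodes). Insert(X,Y,T) and Delete(X,Y,H) follow the
published operator definitions (clique and blocking conditions); after each
move the pattern is rebuilt (PDAG → consistent DAG extension → completed
pattern → knowledge orientations → Meek closure). Forward and backward
phases alternate until neither improves the score — a cheap extension of
the classical two-phase schedule that escapes some finite-sample local
optima. For undirected edges both `Delete(X,Y,·)` and `Delete(Y,X,·)` are
evaluated (they differ at finite samples). Ties are broken
lexicographically on (source, target) for determinism. The exhaustive
oracle enumerates all knowledge-admissible DAGs (≤ 5 nodes), scores them,
and returns the completed pattern of the argmax; tied distinct equivalence
classes are all reported. Greedy-vs-oracle agreement is a *statistical*
property: the acceptance suite requires ≥ 95 agreement out of 100 random
3–4-node problems at n = 2000, and genuine local optima (observed rate
about 2–3 %) are an expected feature of GES at finite samples, not a
defect.

**FCI.** PC-stable skeleton pruning with conditioning sets of increasing
size drawn from current adjacencies (depth unlimited by default, settable);
pairs forbidden in both directions start disconnected. The full
possible-d-sep re-pruning stage is implemented and on by default
(`skip_pdsep = TRUE` gives the cheaper variant); after it, orientation
restarts from circle marks. Orientation: knowledge endpoints, unshielded
colliders (R0), then rules R1–R4 plus the tail-completion rules R8–R10 to
closure. Selection-bias rules R5–R7 are deliberately omitted — no selection
variables are modelled. Collider conflicts are resolved
first-orientation-wins in a deterministic triple order and logged on the
output (`collider_conflicts` attribute), mirroring the error-propagation
behaviour the benchmark documents.

**SEM.** "The model's suggestion" is operationalized as the largest *exact*
BIC improvement on refit, not a Lagrange-multiplier modification index:
refits are per-equation least squares and essentially free at this scale,
and the exact improvement is the quantity the modification index
approximates (`method = "mi"` provides the score-test approximation
`n·r²` for comparison). The stepwise search adds the top candidate while
improvement is positive, with a hard cap (5 in the recovery study; no cap
in the discovery scenario beyond no-improvement). Equal-improvement
direction ties (e.g. both directions of a single correlated pair) are
broken lexicographically and flagged — they are a real identifiability
failure of the single-edge search space, and the flag is how the package
reports it. Improvements equal up to 1e−8 count as ties so the tie-break is
numerically stable.

## Evaluation metrics

"Contradiction" is formalized as *an arrowhead at the gold cause's end*:
with gold `X→Y`, a candidate carrying an arrowhead at X (reversed,
bidirected, or circle-arrow into X) is incorrect; tail-arrow in the gold
direction is correct; everything else (undirected, circle-circle, `X o-> Y`,
`X o-- Y`) is semi-correct. This makes a bidirected edge incorrect — it
asserts pure confounding, contradicting direct causation — while circle
marks remain non-contradictory. Precision is (correct + semi)/reported,
recall is (correct + semi)/8; an empty graph reports recall 0 and NA
precision. Occurrence rates are adjacency-level (orientation-blind) across
bootstrap graphs; orientation stability appears only through the consensus
graph's majority-mark rule (ties → circles), with inclusion at ≥ 80 %
occurrence. Because it is ambiguous whether published precision figures
average per-bootstrap counts or score the consensus graph, the report emits
both (`mean_precision` and `consensus_score`).

## Numerical and reproducibility choices

- Covariances use the maximum-likelihood convention (denominator n) so BIC
  and SEM likelihoods share one scale.
- Score improvements below 1e−10 are treated as zero (no move).
- Every simulation function requires an explicit seed; experiment
  replicates use `derive_seed(master, k) = (master·10007 + 31k) mod
  (2^31−1)`, so replicate k is reproducible in isolation and reports are
  byte-identical across reruns of a master seed.
- Bootstrap covariances are recomputed from resampled participants (the
  resampling unit is the participant, not the covariance).
- Algorithm failures on a replicate (e.g. singular bootstrap covariance)
  are logged and excluded from averages, not fatal.

## A note on sign flips

Structure recovery is invariant to *negating a variable* (flipping every
coefficient adjacent to it), which yields an isomorphic distribution; the
test suite checks exactly this. Arbitrary per-edge sign patterns are not an
invariance: they change the distribution and can create near-cancelling
paths (direct and indirect effects of opposite sign), i.e. near-unfaithful
models on which any score-based search legitimately returns a sparser
graph. The default signs avoid such cancellation; users overriding signs
should be aware that sign *patterns* are part of the stated world.

## Known limitations

- The coded 0/1/2 diagnosis is consumed as a continuous column by all
  arms; thresholding attenuates correlations into DX and is the main gap
  between the generator's latent model and what the searches see. Because
  DX is a sink in the gold graph, no conditional independence among other
  variables requires conditioning on DX, so the coarsening cannot create
  spurious adjacencies in population — but it does weaken edges into DX at
  small n.
- FCI here is the full FCI with R8–R10; which exact variant the original
  Tetrad runs used is unknown, so mark-level agreement with those runs is
  not guaranteed (adjacency-level behaviour is the tested surface).
- The exhaustive oracle is limited to 5 nodes by design; it exists to
  certify the greedy search, not to scale.
- Published headline precision/recall values from the clinical cohort are
  out of scope by construction: the underlying data are access-controlled,
  and the package's claims are about algorithm behaviour on the calibrated
  synthetic world.
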