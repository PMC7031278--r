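# adcausal

Causal structure discovery benchmarks on the Alzheimer's biomarker cascade.

## The problem

Clinical intervention requires causal, not merely associative, relationships.
Causal structure discovery (CSD) algorithms promise to learn a causal graph
from observational data — but how well do they do on realistic cohort data,
and how much does background knowledge help? Alzheimer's disease is a good
model system for this question because the biomarker cascade is well
understood: amyloid-beta deposition (low CSF ABETA) is an early event driven
by age and APOE ε4 allele count; it drives tau pathology (CSF PTAU) and
neurodegeneration (FDG-PET metabolic decline); tau and metabolism drive the
clinical diagnosis (CN/MCI/AD); education buffers cognition. That knowledge
fixes a **gold-standard DAG** over
`{AGE, SEX, EDU, APOE4, ABETA, PTAU, FDG, DX}` with 8 directed edges
(SEX is included but isolated):

```
AGE → ABETA ← APOE4,  ABETA → PTAU,  ABETA → FDG,  PTAU → FDG,
PTAU → DX,  FDG → DX,  EDU → DX
```

`adcausal` rebuilds this benchmark as a tested R package on **synthetic
cohorts**: a linear-Gaussian structural model on the gold-standard graph,
calibrated in closed form so every marginal matches the published cohort
summary statistics (e.g. AGE 74.09 ± 7.46 years, FDG 1.22 ± 0.17, APOE4
class mix 54/36/10 %, diagnosis mix CN/MCI/AD = 31/46/23 %), for both
cross-sectional (n = 1008) and two-visit longitudinal (n = 266) designs.

## What it implements

- **graph model** — one `mixed_graph` container for DAGs, CPDAGs and PAGs
  (endpoint marks: tail `-`, arrowhead `>`, circle `o`), Tetrad-style text
  I/O (`A --> B`, `A o-> B`, `A <-> B`, ...), d-separation, CPDAG
  conversion with Meek-rule closure.
- **three search arms**
  - `fges_search()` — serial greedy equivalence search maximizing the
    decomposable Gaussian BIC
    `score(child | parents) = −n·ln σ̂² − c·(|parents|+1)·ln n`,
    with the published insert/delete operator validity conditions, plus an
    exhaustive enumeration oracle (`exhaustive_best_cpdag()`) for ≤ 5 nodes.
  - `fci_search()` — constraint-based FCI: PC-style skeleton pruning with
    Fisher-z tests (`z = atanh(r)·√(n−|S|−3)`), possible-d-sep re-pruning,
    collider orientation and rules R1–R4 + R8–R10, producing a PAG.
  - `stepwise_search()` / `recovery_experiment()` — the SEM arm: recursive
    path models fit by per-equation least squares, candidate edges ranked
    by exact BIC improvement on refit, and the edge-deletion recovery study
    (delete 1 or 2 gold edges, allow ≤ 5 additions, report full-recovery
    rate and precision/recall).
- **background knowledge** — level 1 (none), level 2 (no edges into
  demographics), level 3 (level 2 + temporal tiers: no edges from the
  24-month visit back to baseline), as forbidden pairs + tiers honored by
  all three arms.
- **evaluation** — the paper-style edge metrics: an edge is *correct*
  (exact orientation match), *semi-correct* (adjacent in gold, orientation
  not contradicted), or *incorrect* (absent pair, or arrowhead at the gold
  cause); precision/recall, bootstrap adjacency occurrence rates, and
  ≥ 80 %-occurrence consensus graphs.
- **experiments** — `run_discovery_experiment()` (100 participant-level
  bootstraps × algorithms × knowledge levels) and `run_recovery_study()`,
  fully reproducible from a master seed.

## Worked example

```r
library(adcausal)

gold <- build_gold_standard("cross_sectional")
cohort <- simulate_cross_sectional(default_parameters(), n = 1008, seed = 7)
cov <- cohort_cov(cohort)

k2 <- build_background_knowledge(2, gold$nodes)  # no edges into demographics
g <- fges_search(cov, k2)
g
#> <mixed_graph: CPDAG, 8 nodes, 8 edges>
#> Nodes: AGE;SEX;EDU;APOE4;ABETA;PTAU;FDG;DX
#>   AGE --> ABETA
#>   EDU --> DX
#>   APOE4 --> ABETA
#>   ABETA --> PTAU
#>   ABETA --> FDG
#>   PTAU --- FDG
#>   PTAU --> DX
#>   FDG --> DX

score_graph(g, gold)
#> $correct      [1] 7
#> $semi_correct [1] 1
#> $incorrect    [1] 0
#> $precision    [1] 1
#> $recall       [1] 1
```

Seven of the eight edges are recovered with their exact orientation; the
`PTAU --- FDG` edge stays undirected because both orientations are in the
same Markov equivalence class (a covered edge), so it scores as
semi-correct — precision and recall are (correct + semi-correct)-based and
both equal 1 here.

The SEM recovery study on the exact population covariance:

```r
run_recovery_study(experiment_config(seed = 1),
                   cov_or_cohort = population_cov_model(n = 1008))$summary
#>   k n_runs full_recovery_rate mean_precision mean_recall
#> 1 1      8              0.875      0.9843750   0.9843750
#> 2 2     28              0.750      0.9452381   0.9598214
```

(The one non-recovered k = 1 run deletes `PTAU → FDG` and re-adds its
Markov-equivalent reversal — the identifiability failure the benchmark is
designed to expose.)

## Command line

```sh
Rscript inst/cli/adcausal.R simulate --n 1008 --seed 1 --out cohort.csv
Rscript inst/cli/adcausal.R discover --algorithm fges --knowledge-level 2 \
    --cohort cohort.csv --out graph.txt
Rscript inst/cli/adcausal.R evaluate --cohort graph.txt --out eval.json
Rscript inst/cli/adcausal.R recover --k 1 --max-add 5 --out recovery.json
Rscript inst/cli/adcausal.R report --algorithm fges,fci,sem \
    --knowledge-level 2 --n-bootstraps 100 --seed 1 --out reports/run
```

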