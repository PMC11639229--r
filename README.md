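# ligandAL

Active-learning campaigns for ligand activity prediction in lead
optimization.

## What problem this solves

Late-stage lead optimization — especially scaffold replacement, where the
molecules still to be designed must deviate from known chemical matter —
historically burns hundreds of synthesized analogs. ligandAL implements and
benchmarks the alternative: an iterative campaign in which a surrogate
affinity model scores the pool of not-yet-made ("future") candidates,
acquires a small batch per round under a dual criterion, absorbs the new
assay values, and refits, until a structurally novel goal compound is
identified. It is written for computational chemists who want to study,
extend or re-run this kind of retrospective campaign on their own
time-stamped structure–activity data or on the built-in calibrated
synthetic benchmark.

## The method in brief

Given compounds with binary fingerprints x, activities y (pIC50) and
synthesis-order indices, each round:

1. **Score** all future candidates: predicted activity ŷ, novelty
   `1 − max Tanimoto` to the training set, and the nearest-neighbor (NN)
   training molecule with its similarity.
2. **Exploit**: among the 200 least-novel (best-covered) candidates, take
   the 10 with highest ŷ.
3. **Informative**: among candidates whose NN is structurally close (top
   100 by NN similarity, or NN similarity ≥ 0.85) *and* potent (NN activity
   ≥ 8.5), take the 10 with *lowest* ŷ — the "surprising" molecules whose
   assay values are maximally corrective.
4. **Refit** on the enlarged training set and report Kendall τ_b, mean
   unsigned error (with bootstrap 95% CIs), kcal/mol error bins (at the
   fixed equivalence 1.5 pIC50 ≡ 2 kcal/mol) and the goal compound's rank.

Round 00 additionally builds N = 5 alternative initial models and picks one
by a probabilistic score: each quality metric (parsimony P, refit τ T,
refit MUE E) is z-scored across models and mapped through the normal CDF Φ,
and the model maximizing `Φ(P)·Φ(T)·(1−Φ(E))` is selected.

Two surrogate predictors ship behind a pluggable contract: a convex
similarity-kernel k-NN model and an additive (ridge-on-bits) model that can
extrapolate beyond the training activity range (the campaign default).

## Worked example

```r
library(ligandAL)

ls  <- generateLandscape(landscapeConfig(seed = 1))   # 1109 compounds
res <- runCampaign(ls$compounds, campaignConfig(seed = 1))

res$reports[, c("round", "nTrain", "nFuture", "futureTau", "futureMue",
                "goalPred", "goalRankPct")]
#>   round nTrain nFuture futureTau futureMue goalPred goalRankPct
#> 1     0    100    1009     0.594     0.423     9.39        1.68
#> 2     1    120     989     0.591     0.394     9.39        1.68
#> 3     2    140     969     0.606     0.352     9.39        1.68
#> 4     3    160     949     0.610     0.345     9.39        1.68
#> 5     4    180     929     0.594     0.358     9.39        1.68
#> 6     5    200     909     0.589     0.361     9.39        1.68
res$goalFoundRound
#> [1] 0
```

Reading the output: the campaign runs six 20-compound selection events
(train grows 100 → 200, i.e. 120 of the 1009 future molecules get "made"),
future-pool MUE improves from 0.42 to 0.36 pIC50 units as acquisition
broadens coverage, and the goal compound — a late, non-dominant-scaffold
molecule of near-maximal activity — is predicted at 9.39 pIC50 (top 1.7% of
the pool) and acquired in the very first selection round; after
acquisition its report fields carry the last pre-acquisition values
forward. A uniform-random baseline (`campaignConfig(selector = "random")`)
almost never acquires the goal within 120 picks.

Other entry points: `pickDiverseActives()` (max-min diverse actives within
the top activity window, e.g. to anchor an alignment hypothesis),
`rankHypotheses()` (ROC-area ranking of hypothesis score vectors, actives
pIC50 ≥ 8.5 vs inactives ≤ 7.5), `readCompoundTable()`/`readSdf()` for real
data, and a shell interface (`inst/scripts/ligandal`) with `simulate`,
`run`, `score`, `select` and `report` subcommands.

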