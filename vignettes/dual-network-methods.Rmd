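---
title: "Dual-network inference of risk-factor hierarchies: models, choices, limits"
author: "consnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-network inference of risk-factor hierarchies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Cross-sectional cohorts of modifiable health-risk variables — symptom scale
totals, diet and activity scores, cardiometabolic self-management measures,
demographics — are highly collinear, and regression on any single outcome
hides that structure inside coefficients. `consnet` estimates two
complementary graphical summaries of one such dataset:

* an **RPCN** (regularized partial correlation network): an undirected graph
  whose edge weights are penalized partial correlations
  $r_{ij} = -\theta_{ij}/\sqrt{\theta_{ii}\theta_{jj}}$ from a sparse precision
  matrix $\Theta$, so each edge is an association conditional on every other
  variable; and
* a **consensus Bayesian DAG**: a directed acyclic graph whose arcs survive a
  deliberately severe double cross-consensus ("2X-Cons") ensemble of
  bootstrap-averaged structure learners, suggesting a directional hierarchy
  among the variables.

Neither graph is causal. The DAG's arrows are probabilistic orientation
evidence under the model class, and the package flags rather than hides the
arcs whose pooled orientation support is weak.

# Data handling

A cohort enters as a CSV plus a JSON schema declaring each variable's role
(continuous / ordinal / categorical), optional admissible range, ordered
levels, discretization exemption, and blacklist membership. Cleaning is
two-stage, and the accounting is deliberately value-level first:

1. **Value screens** (`apply_screens()`) null individual offending cells
   (e.g. BMI below 13 or above 90, activity below 1 or above 15,000 METS,
   alcohol at or above 70 weekly units) and log each removal against its
   rule.
2. **Complete cases** (`complete_cases()`) then drop any row with a missing
   cell. There is no imputation anywhere; the analysis set is complete
   observations only, and the log arithmetic `n_in = n_out + rows dropped`
   is asserted by tests.

Ambiguity resolved here: when a screened value sits in an otherwise complete
row, we null the value and let the complete-case pass remove the row — the
two counts stay separately reported, matching the value-then-row accounting
style of the exclusion reports this design follows.

# The four transformed views

The ensemble deliberately varies the data representation, because structure
learners are sensitive to marginal shape:

* **disc3 / disc5** — mutual-information-preserving (Hartemink)
  discretization into 3 or 5 ordered levels: 100 equal-width seed bins per
  variable (`initial_bins = 100`, interval seeding), then greedy adjacent-bin
  merges, round-robin over variables in schema order, each merge chosen to
  minimize the loss of total pairwise mutual information. The MI objective
  runs over the variables being discretized — exempt variables (typically
  nominal demographics, kept on their original codes to preserve factor
  meaning) are not part of it, mirroring the reference implementation where
  they are simply not passed to the discretizer. The one exception: if only a
  single variable is being discretized the objective would be empty, so
  exempt columns then act as fixed reference columns. Codes are `1..levels`
  in value order, so discretization is monotone.
* **npn** — nonparanormal shrinkage: every cell becomes
  $\Phi^{-1}(r/(n+1))$ of its within-column average rank, then all columns are
  divided by one common factor (the SD of the tie-free reference column), so
  untied columns have unit SD. Being rank-based, it is invariant to monotone
  marginal transforms.
* **int** — inverse normal transformation, the univariate counterpart:
  percentile $(\mathrm{rank}-1)/(n-1)$ per column, rows attaining a
  percentile of exactly 0 or 1 anywhere removed (they would map to
  $\pm\infty$), survivors mapped through $\Phi^{-1}$. Removal is row-wise,
  consistent with a complete-observation analysis set. Tie convention:
  average ranks, in both npn and int (the source methods are silent; the
  choice is recorded here and treated as configuration, not fact).

All four transforms are deterministic, and the suite records a provenance
hash of the source table.

# The RPCN

`correlation_auto()` feeds `ebic_glasso()`. The default correlation is the
rank-latent estimator: Spearman's $\rho$ mapped by $2\sin(\pi\rho/6)$ to the
latent-Gaussian scale. This is a deliberate substitution for full polychoric
maximum likelihood (out of scope); it shares the key property of monotone
invariance and is close to polychoric values for ordinal data with several
levels. A nearest-PSD repair (eigenvalue clipping + rescaling to unit
diagonal) is applied when needed and flagged.

The graphical lasso runs along 100 log-spaced penalties from
$\lambda_{\max}$ (largest absolute off-diagonal correlation — the smallest
penalty emptying the graph) down to $0.01\,\lambda_{\max}$, and the model
minimizing

$$\mathrm{EBIC} = -2\,\ell(\hat\Theta) + E\log n + 4\gamma E \log p$$

is selected, with $E$ the number of active upper-triangle precision entries
and $\gamma = 0.5$ by default — the conservative setting that trades false
positives for false negatives. (The source analysis labels this
hyperparameter $\lambda$; in the EBIC literature it is $\gamma$. It is housed
here as `ebic_gamma` and the naming clash is documented, not resolved.)

Diagnostics:

* **Centrality** — strength $\sum_j |w_{ij}|$, expected influence
  $\sum_j w_{ij}$, and shortest-path closeness/betweenness on distances
  $1/|w_{ij}|$. Closeness is harmonic (sum of inverse distances, unreachable
  nodes contributing 0) so disconnected graphs need no special casing;
  betweenness counts weighted shortest paths. Whether the original analyses
  used weighted or unweighted path counting is not stated; inverse-weight
  distances are this package's choice.
* **Predictability** — each node regressed (unpenalized) on its RPCN
  neighbors: $R^2$ for numeric nodes, normalized accuracy above the marginal
  mode for categorical ones, 0 for isolated nodes. This is a simplification
  of the mixed-graphical-model nodewise statistic (the full mixed model is a
  non-goal).
* **Edge accuracy** — non-parametric bootstrap (row resampling, full
  refit): per-edge mean, percentile 95% CI, and the conditional mean over
  resamples where the edge is present.
* **Centrality stability** — case-dropping bootstrap over the drop grid
  $\{0.05, \dots, 0.75\}$: the CS-coefficient is the largest drop proportion
  at which at least 95% of subsamples keep a Spearman correlation of at
  least 0.70 with the full-sample centralities, required to hold at every
  smaller drop as well (a conservative reading that makes CS monotone).
  Spearman rather than Pearson because centralities are rank-interpreted.
  Reports flag CS ≥ 0.25 as interpretable and ≥ 0.50 as good.

# Structure learning

Four learners over each view (16 cells): hill climbing (**hc**), tabu search
(**tabu**), and the hybrids **mmhc** and **h2pc**. Scores are decomposable
BIC — multinomial for the discretized views, linear-Gaussian for npn/int —
with per-node caches keyed on parent-set bitmasks. The source analysis names
the learners but not scores, tests, or search settings; ecosystem defaults
are adopted and every choice surfaces in the run manifest.

* Hill climbing starts from the empty graph; single-arc additions,
  deletions and reversals must keep acyclicity, respect the blacklist, and
  strictly improve the score. Ties break lexicographically by `(from, to)`,
  so runs are exactly reproducible; no random restarts.
* Tabu search adds a fixed-length memory of visited structures and up to
  `max_worsening_moves` non-improving moves (defaults 10 and 10), returning
  the best structure visited. With both set to 0 it reduces exactly to hill
  climbing (tested).
* The hybrids first learn an undirected skeleton — MMPC (max-min
  parents-and-children with subset-based CI filtering) or an HPC-flavored
  variant (parents-and-children superset from marginal dependence pruned by
  single-variable conditioning, expanded one neighborhood, then the same
  subset-filtered PC search) — with G²/mutual-information tests for discrete
  views and Fisher-z partial-correlation tests otherwise, at α = 0.05, and
  AND-symmetrization. Hill climbing then restricts arc *additions* to
  skeleton pairs (deletions/reversals free). The HPC variant is a pragmatic
  reduction of the published algorithm (whose spouse-recovery stage matters
  most in high dimensions); with ~20 variables it behaves like a
  pool-restricted MMPC and is documented as such.

Greedy search is a local method: on structures where a collider's parents
are themselves strongly linked, hill climbing can legitimately stop in a
score-equivalent local optimum that tabu escapes. The oracle-equivalence
tests therefore use chain/tree structures, where the greedy optimum and the
exhaustive-enumeration optimum provably coincide; this is a property of hill
climbing, not a defect.

The **blacklist** forbids incoming arcs to declared variables (age, gender,
education, and the recent-stressor count in the emulated design). Blacklisted
variables may still emit arcs, and arcs between two blacklisted variables are
not forbidden — consistent with the observed behavior of the reference
results, where blacklisted demographics parent each other.

# The 2X-Cons ensemble

Per cell, `B` bootstrap row-resamples are drawn and the learner rerun; per
unordered pair, **strength** is the fraction of resampled structures
containing the edge in either orientation and **direction** the oriented
fraction among those (a learner emitting an undirected representative would
count half to each side — defensive only, as all four learners emit DAGs).
Ad-hoc thresholding retains pairs with strength ≥ 0.85 whose majority
orientation was learned by a strict majority of all `B` bootstraps
(`floor(B/2)+1`, i.e. 5,001 of 10,000); a 50/50 orientation split drops the
pair as direction-unresolved. This converts every averaged subnetwork into a
DAG, which is audited (an audit failure is an error naming the cycle — it
should be unreachable, and the audit is kept as a safety contract).

The consensus rule: an arc qualifies only if retained under **all four
algorithms within at least three of the four transformations**. That reading
(rather than "any 4 algorithms + any 3 transformations marginally") is the
one that yields the stated minimum of 12 of 16 cells, and the package's
`consensus_min_cells()` derives 12 by enumerating all $2^{16}$ presence
patterns against the implemented predicate.

Per consensus arc, with $k$ the number of containing subnetworks out of
$K = 16$:

* `learned_strength` / `learned_direction` — mean strength / oriented
  fraction over the $k$ containing cells (orientation chosen by the pooled
  majority; exact ties break lexicographically);
* `grand_strength` / `grand_direction` — the same means over all $K$ cells
  with absent cells contributing zero, so grand = learned × k/K exactly
  (cross-checked to 1e-12 at run time).

$k$ counts containment regardless of per-cell orientation — required for
coherence, since pooled grand direction below 0.5 (which the package flags)
can only arise when cells disagree about orientation. Per-cell RNG seeds are
derived from the master seed and the cell *labels*, so adding or reordering
cells never perturbs the others.

# Synthetic cohorts and what a green test establishes

`make_island_like()` generates a 20-variable cohort from a planted
linear-Gaussian SEM whose graph mirrors a plausible
stress → mental-health → behavior hierarchy (26 arcs), with marginal maps
chosen once to emulate the emulated study population's structure: bounded
scale scores via binomial quantile maps (e.g. a 0–21 symptom scale with mean
≈ 3–4, a 0–14 diet score with mean ≈ 9.9), heavy-tailed activity
(log-normal) and alcohol (gamma) measures, ordinal demographics with
realistic level frequencies, and four sink-forbidden variables. All marginal
maps are monotone in the latent variables, so rank-based stages see the
planted dependence exactly.

Effect sizes: nominal standardized coefficients of 0.7 per arc (the middle
of the declared easy regime 0.5–0.8), with each node's coefficient vector
rescaled — preserving ratios — wherever its parents would explain more than
64% of variance. The cap is a feasibility requirement: with correlated
parents, three coefficients of 0.7 would demand negative noise variance, so
"standardized effects in [0.5, 0.8]" cannot hold arc-wise for every
multi-parent node of a realistic graph; the per-node R² cap is the
compromise, set once and not revisited.

What generated data does *not* emulate: item-level psychometrics,
missingness mechanisms, cohort selection bias, non-Gaussian dependence
beyond monotone marginals. A green recovery test therefore establishes that
the pipeline recovers planted monotone-Gaussian hierarchies at realistic
size and skew — not that any real cohort's inferred hierarchy is true.

The acceptance suite runs the full grid at B = 200 (scaled down from the
reference 10,000 for a single-CPU budget; thresholds rescale as counts of
B). The consensus graph on the planted cohort attains skeleton F1 ≥ 0.8 with
precision 1.0 in that regime — the rule is severe, so its errors are
omissions, which is exactly its design intent.

# Numerical choices and degenerate inputs

* Precision entries below 1e-10 count as zero for edge counting; partial
  correlations are clipped to ±(1 − 1e-12).
* EBIC ties select the sparser (earlier, more penalized) path point.
* Strict-improvement threshold in search: 1e-8 on score deltas.
* Constant columns: error in npn/int/correlation (undefined ranks); a
  single-category warning in discretization.
* A correlation matrix failing PSD by more than −1e-8 after repair is an
  error; repairs are flagged in the object.
* Resample failures: edge bootstrap skips and errors above 10% failures;
  arc-strength bootstrap redraws once, then counts the resample as
  structure-absent with a warning.

# Known limitations

* Rank-latent correlation is a stand-in for polychoric ML; for binary
  variables its bias is larger than for 5-level ordinals.
* The H2PC restrict phase is a documented variant, not the published
  algorithm.
* Hill climbing is a local search (see above); the ensemble's bootstrap
  averaging, not the single run, carries the robustness.
* CS-coefficients at small B are coarse: with B = 20 per drop level, one
  aberrant subsample decides the 95% criterion.
* The consensus rule's severity means moderate-signal arcs (standardized
  effects near 0.3–0.4 after feasibility rescaling, or variables with
  extremely concentrated marginals) are routinely omitted; interpret absence
  as "not robustly supported", never as evidence of independence.
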