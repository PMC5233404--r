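---
title: "Pathway-drug network propagation for drug repositioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-drug network propagation for drug repositioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(padnet)
```

## The problem and the model

Drug repositioning asks which already-approved drugs might treat a disease
they were not developed for. padnet implements a pathway-centric,
network-based answer built from two kinds of expression evidence:

1. **Disease evidence.** Case/control expression studies of the disease
   are each scored by gene set enrichment analysis (GSEA): genes are ranked
   by a signal-to-noise statistic and each pathway receives a weighted
   Kolmogorov-Smirnov enrichment score (ES) with a permutation p-value.
   Pathways significant at nominal `p < 0.01` in at least one study form
   the *disease-specific pathway* set — taking the union across studies
   buys robustness that no single microarray study provides.
2. **Drug evidence.** Drug-treated versus vehicle expression profiles
   (CMap-style) give, for every drug, an ES on every pathway. The
   resulting pathways-by-drugs matrix is read as a weighted bipartite
   graph: pathway nodes `U`, drug nodes `V`, edge weight the strength of
   the drug-pathway association.

The core premise is that drugs treating the same phenotype perturb the
same pathways. It is operationalized as semisupervised label propagation:
disease pathways and the handful of known treatment drugs are labeled 1,
everything else 0, and labels diffuse over the normalized bipartite graph

$$B = D_u^{-1/2}\, W\, D_v^{-1/2},$$

with the coupled Jacobi updates

$$f_v^{t} = (1-\alpha)\,y_v + \alpha \sum_{u} B_{uv}\, f_u^{t-1},
\qquad
f_u^{t} = (1-\alpha)\,y_u + \alpha \sum_{v} B_{uv}\, f_v^{t-1},$$

both sides reading the previous iterate. Because the spectral norm of `B`
is at most 1, the iteration is a contraction for any damping
$\alpha < 1$ and converges to the unique fixed point
$f = (1-\alpha)(I - \alpha M)^{-1} y$ with
$M = \begin{bmatrix} 0 & B \\ B^\top & 0\end{bmatrix}$;
`propagate_closed_form()` computes that solve directly and doubles as an
exact cross-check of the iterative solver.

Final drug scores are Z-normalized (population standard deviation) and
converted to one-sided upper-tail Gaussian p-values; drugs with
`p < 0.001` are the repositioning selection, and those not already known
are the novel candidates. A separate *validation stage* triages candidates
on a heterogeneous drug-gene network (chemical similarity, drug-target and
protein-protein edges) using degree centrality, unnormalized betweenness
and weighted PageRank.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `p_threshold` (enrichment) | 0.01 | per-study pathway significance for the union |
| `n_perm` | 1000 | permutations per study; floors the attainable p at ~1/1001 |
| `weight_exponent` | 1 | hit weighting in the running sum (0 = classic KS) |
| `min_overlap` | 5 | smallest pathway/dataset gene overlap scored |
| `weight_transform` | `"abs"` | how signed ES becomes an edge weight |
| `alpha` | 0.8 | diffusion damping; 0 returns the labels unchanged |
| `tol`, `max_iter` | 1e-6, 1000 | convergence of the Jacobi iteration |
| `p_candidate` | 0.001 | Gaussian-tail cutoff for the selection |
| `weight_min` | 0.4 | strict edge filter of the validation network |
| `neighbor_cap` | 40 | strongest edges kept per drug node |
| `damping` | 0.85 | PageRank damping on the validation network |

Design choices made where the method leaves room, with our reasoning:

* **Ranking metric.** The GSEA step uses the canonical signal-to-noise
  statistic with each class standard deviation floored at
  `0.2 * |class mean|` (plus a tiny absolute floor), which keeps
  low-variance genes from dominating log-scale data. Ties are broken by
  gene symbol so rankings are fully deterministic.
* **Permutation scheme.** Phenotype labels are permuted and the whole
  ranking recomputed — the null that respects gene-gene correlation. Below
  7 samples per class the label space is too small and the null falls back
  to gene-set permutation, the convention GSEA itself uses. p-values use
  the add-one estimator `(1 + extreme)/(1 + same-sign)`, so they are never
  zero (reported zero p-values in the literature are an artifact of plain
  `x/n` estimators); the normalized ES divides by the mean |ES| of the
  same-sign permutations and is `NA` when no permutation shares the sign.
* **Negative enrichment.** A strongly negative ES is still evidence that
  the drug engages the pathway, so the default edge weight is `|ES|`;
  `weight_transform = "positive"` is available when only
  same-direction enrichment should count. No sparsification is applied by
  default (`threshold = 0`): the source matrix is dense.
* **Sidedness of the candidate test.** One-sided upper tail: only
  unusually *high* propagation scores are evidence for repositioning, and
  only that choice reproduces the published (Z, p) selections. Z-scores
  use the population (divide-by-n) standard deviation; at realistic drug
  counts the distinction from the sample sd is far below reported
  precision, but the choice is fixed.
* **Propagation damping.** The diffusion's own damping is not prescribed
  by the validation stage's PageRank value (0.85); we default to
  `alpha = 0.8` and record it in `glance()` output. At the fixed point the
  starting vector is irrelevant; we start at `f = y` and use Jacobi
  (simultaneous) updates, matching the coupled update equations exactly.
* **Validation-network semantics.** The weight filter is strict
  (`> 0.4`), raw 0-900 interaction scores must be rescaled explicitly, an
  edge between two drugs must rank within the 40-edge cap for *both*
  endpoints (so the cap is a true per-drug guarantee), duplicate edges
  keep their maximum weight, and gene-gene edges survive only while both
  endpoints stay attached to the drug layer. Betweenness is reported
  unnormalized over unordered pairs (matching the integer scale on which
  such tables are published); PageRank is reported raw (sums to 1) and
  min-max scaled, the scaling flagged `NA` when all nodes tie.

## What the synthetic generator emulates

Real inputs for this framework are multi-gigabyte public resources
(expression archives, drug-perturbation compendia, interaction databases).
`simulation_scenario()` plants their statistical structure at desk scale;
its defaults are the package's study conditions and every draw is
determined by the scenario seed.

* **Expression:** four independent studies, 2000 genes, 30 + 30 samples.
  Controls are standard normal; genes of the 10 planted disease pathways
  (out of 200 of size 15-40) are shifted by 2 sd in cases. Because null
  pathways draw members uniformly, they share genes with planted ones and
  a sizable fraction reaches `p < 0.01` — the integrated union is
  therefore realistically noisy (roughly 140-150 pathways), not a clean
  oracle set.
* **Drug matrix:** 1000 drugs; 5 known + 5 candidate drugs carry
  near-saturated associations (|ES| ~ 0.9, random sign) on the planted
  pathways over weak background noise (sd 0.04). The planted fraction
  (1%) mirrors the sparse hit rate of a real repositioning screen; an
  earlier design with 10 planted drugs in 100 makes the `p < 0.001` rule
  unreachable in principle — with a fraction $q$ of equally high scorers
  the best attainable Z is $\sqrt{(1-q)/q}$, which is 3.0 at $q = 0.1$,
  below the 3.09 the rule demands.
* **Validation network:** known + candidate drugs plus synthetic genes;
  background edges are Erdős–Rényi with Uniform(0.2, 0.6) weights (so the
  0.4 filter removes about half), and planted hub drugs attach strongly
  (weights 0.7-0.99) to the known drugs and most genes.

What passing these simulations does *not* show: robustness to microarray
normalization artifacts, batch effects, probe-mapping loss, correlated
gene noise, drug-name vocabulary mismatch (the package surfaces unmatched
ids for this reason), or the heavy-tailed degree structure of real
interaction databases. The generator is a correctness and power harness,
not a biological benchmark.

## Numerical choices and degenerate inputs

* The running-sum ES is computed from hit positions in O(k log k); when
  every hit weight is zero (flat metric with positive exponent) hits fall
  back to equal increments, the classic KS statistic. A set covering the
  whole ranking scores ES = 1. No-overlap sets are an error, never ES = 0.
* The permutation engine vectorizes the per-permutation signal-to-noise
  over all permutations as matrix products and evaluates the
  per-permutation, per-set running sums in C++; the R reference
  implementation is kept in the test suite and must agree to machine
  precision.
* Probes without a mapped symbol are dropped; multi-probe genes are
  averaged. Genes with missing values are dropped by default
  (`na_action = "omit"`) or row-mean imputed on request.
* Isolated nodes are removed during bipartite construction because the
  degree normalization is undefined at degree zero; encountering one later
  is an error, not a silent repair.
* Propagated scores are provably nonnegative with
  $\lVert f\rVert_2 \le \lVert y\rVert_2$; individual scores can exceed 1
  on star-like graphs (a hub pathway with $k$ labeled unit-weight drug
  neighbors reaches $f_u = \alpha\sqrt{k}/(1+\alpha)$), so no [0, 1] clamp
  is applied or assumed.
* Constant score vectors make the Z-score undefined and raise an error
  that the command-line `score` stage converts to a nonzero exit.

## Problem sizes used by the checks

The bundled tests and the acceptance script run the full pipeline on the
default scenario over 20 seeds (about 7 s per seed), agreement checks of
the iterative against the closed-form propagation on 100 random bipartite
graphs up to 100 nodes per side, brute-force enrichment-score comparisons
on 100 random rankings, and a null-calibration study of 200 repetitions at
500 permutations each. These sizes give stable statistics while keeping a
complete run in a few minutes on one core.

## A worked example

```{r example, eval = FALSE}
sc <- simulation_scenario(seed = 11)
expr <- simulate_expression_datasets(sc)
dm <- simulate_drug_phenotype_matrix(sc)

res <- reposition_drugs(expr$datasets, expr$gene_sets, dm$matrix,
                        known_drugs = dm$known_drugs,
                        n_perm = 1000, seed = 11)
glance(res$scores)
res$candidates$novel
autoplot(res$scores)

# triage candidates on a validation network
vn <- simulate_validation_network(sc)
net <- assemble_validation_network(vn$edges, weight_min = 0.4,
                                   neighbor_cap = 40)
topology_metrics(net, damping = 0.85) |>
  dplyr::filter(kind == "drug")
```

## Known limitations

* The package consumes preprocessed expression matrices; normalization of
  raw array data and batch-effect removal are upstream concerns.
* Nominal p-values are used exactly as the selection rules require —
  deliberately uncorrected for multiple testing at both stages.
* The drug-pathway matrix is taken as given (or simulated); collapsing
  replicate drug-perturbation instances across cell lines and doses into
  one contrast per drug is outside the package's scope.
* Published validation-network metrics depend on database snapshots that
  cannot be reconstructed exactly; the bundled 57-node network is a
  partial reconstruction whose faithful quantities are the two documented
  candidate neighborhoods and the hub drug's degree, nothing more.
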