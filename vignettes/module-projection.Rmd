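---
title: "Scoring expression changes against co-expression module signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring expression changes against co-expression module signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modproj)
```

## The method

Differential-expression analysis by per-gene thresholding discards the
many genes whose fold changes are individually small. Co-expression module
projection recovers that information: if a library of modules — sets of
co-regulated genes with non-negative weights, such as those obtained by
independent component analysis of a large expression compendium — is
available as a feature-by-module weight matrix $W$, then a comparison's
whole log fold-change profile can be scored against every module at once.
A module registers as perturbed when its member genes move coherently,
even when no single member passes a fold-change cutoff.

For one genotype-pair comparison the pipeline is:

1. **Collapse to gene level.** Module libraries derived from microarrays
   are indexed by probe sets. Probes mapping to the same gene are averaged
   per module (zeros included in the mean), giving a gene-level matrix.
2. **Standardize.** The logFC vector $v$ is centered to mean 0 and scaled
   to unit variance (sample standard deviation, denominator $n-1$), so
   projections are comparable across comparisons of different amplitude.
3. **Restrict.** Matrix and vector are cut down to their shared gene ids,
   in a canonical lexicographic order.
4. **Project.** For each module column $m$, the scalar projection
   $s_m = v \cdot m \,/\, \lVert m \rVert_2$ measures how far $v$ extends
   along the module direction.
5. **Permutation null.** The gene-label-to-value assignment of $v$ is
   shuffled (100 times by default, over the shared genes only) and each
   shuffled vector is projected. The null mean $\hat\mu_m$ and sample
   standard deviation $\hat\sigma_m$ of a module's permutation scalars
   give $z_m = (s_m - \hat\mu_m)/\hat\sigma_m$.
6. **Score.** A module is called significant when $z_m \ge +3$ or
   $z_m \le -3$ and its p-value is $\le 0.05$.

The standardization in step 2 makes every permuted vector a re-labeling
of the same value multiset, so the null is exchangeable by construction;
no re-standardization is needed per permutation.

```{r pipeline}
sc <- synthetic_scenario(seed = 7, n_genes = 1000, n_probes = 1100,
                         n_modules = 50, nnz_per_module = 30,
                         planted = planted_signal("M_7-", beta = 8, sign = -1))
mat <- collapse_probes(gen_module_matrix(sc), gen_probe_map(sc))
res <- run_projection(gen_lfc(sc, mat), mat, n_perm = 100, seed = 99)
head(res[order(-abs(res$z)), ])
```

## Parameters that matter

* `n_perm = 100` permutations. The empirical p-value then has floor
  $1/(n_\text{perm}+1) = 1/101 \approx 0.0099$, comfortably below the
  0.05 significance cutoff, and $\hat\sigma$ is estimated from 100 draws.
  More permutations sharpen $\hat\sigma$ but the default matches the
  standard practice for this statistic.
* `z_cut = 3`, `alpha = 0.05` (dimensionless; both inclusive). Because
  $|z| \ge 3$ already implies a small p-value under either p-value
  definition, the rule is driven by the Z cutoff in practice.
* `normalize = TRUE`: divide the dot product by the column norm (the
  textbook scalar projection). The upstream literature is not explicit
  about this normalization, so a raw-dot-product switch is provided; Z
  scores are invariant to any per-module rescaling, so the switch affects
  only the reported scalars, not the calls.
* `weight_cut = 3` for discretizing modules into gene sets (inclusive).
* DEG thresholds `lfc_cut = 0.5` (log2 units) and `alpha = 0.05` on the
  BH-adjusted p, both inclusive.
* CPM filter: retain genes with CPM $\ge 1$ in at least `min_samples`
  samples. How many samples must pass is commonly left unstated in
  methods sections; the default of 4 matches a four-replicate-per-group
  design and is configurable. Per-sample and per-group readings are both
  expressible through this one knob.
* Network cutoffs `p_cut = 0.05`, `q_cut = 0.1`, `overlap_cut = 0.6`
  (inclusive, the EnrichmentMap convention), and a recurrence filter
  keeping nodes enriched in at least 4 comparisons of a six-comparison
  design.

## The synthetic-data generator

Real inputs for this kind of analysis are an edgeR results table per
comparison and a published module matrix; neither is redistributable at
package scale, and planted ground truth is needed for testing anyway. The
generator therefore emulates the statistical structure the analysis
assumes:

* a sparse non-negative probe-by-module matrix with exactly
  `nnz_per_module` positive weights per column, drawn from
  Gamma(shape = 2, scale = 1.5). The gamma parameters are a modeling
  choice, not a reproduction of any published matrix (whose weight
  distribution is not printed); they are chosen so typical weights
  straddle the discretization cutoff of 3 and thresholding is exercised
  non-trivially;
* a surjective many-to-one probe-to-gene map, so probe averaging is
  always exercised when `n_probes > n_genes`;
* logFC vectors $v_g = \sum_k \beta_k \, \text{sign}_k \, m_{gk}/\lVert
  m_k \rVert_2 + \varepsilon_g$ with i.i.d. Gaussian noise. Planting
  along the L2-normalized column makes $\beta$ the expected projection
  scalar of the clean signal, so power is analytically predictable;
* paired vectors sharing the planted component with independent noise,
  emulating two contrasts that probe the same biology (e.g.
  mutant-vs-wildtype and mutant-vs-rescue);
* DGE tables whose p-values come from a two-sided normal test of
  `logFC / (dispersion / sqrt(n))`. Only the table shape and ranking
  behavior matter downstream, so no count-level negative-binomial model
  is simulated.

What passing tests on this generator do **not** show: behavior under
correlated noise across genes, library-size artifacts, modules with
heavy-tailed or bimodal weights, or probe-to-gene maps with unmapped
probes — real-data features outside the generator's scope. The `+`/`-`
module-label suffixes are opaque labels here; the actual sign-splitting
of independent components into paired modules belongs to the upstream
compendium analysis and is out of scope.

## Numerical choices

* Sample standard deviation ($n-1$) everywhere — vector standardization
  and $\hat\sigma$ — for internal consistency; the difference from the
  population form is negligible at realistic sizes but must be pinned
  down for exactness tests.
* Empirical p-value with add-one correction,
  $p = (1 + \#\{r: |s_r - \hat\mu| \ge |s - \hat\mu|\})/(n_\text{perm}+1)$;
  ties count as extreme (conservative). The normal approximation
  $2\Phi(-|z|)$ is also reported; it is clamped at the smallest positive
  double to avoid underflow to 0 at extreme $z$. Which p-value feeds the
  significance rule is a parameter (`p_type`), empirical by default: it
  is the defensible choice for a 100-draw null, and both definitions
  satisfy $p \le 0.05$ whenever $|z| \ge 3$, so the calls are insensitive
  to the choice.
* Modules whose restricted column is all zero, or whose permutation
  scalars are constant ($\hat\sigma = 0$, e.g. equal weight on every
  shared gene), get `NA` Z-scores and are never significant.
* Constant fold-change vectors are a degenerate-input error, not a
  silent division by zero.
* Permutations are drawn after feature restriction (values shuffled over
  shared gene labels only), matching the stage order above; permutation
  $r$ consumes the $r$-th block of a single seeded stream, so the null
  table does not depend on how many modules are scored.
* Enrichment: plain one-sided hypergeometric tail by default; the EASE
  variant (overlap count reduced by one) is a flag. Node p/q values are
  interface-compatible with annotation-chart tools, not value-compatible
  with any specific one, whose internal clustering and background
  construction are out of scope. The background universe is always an
  explicit argument — genome-wide versus expressed-genes backgrounds give
  different p-values and the choice is the user's.
* Concordance between two comparisons defaults to the modules significant
  in **both** (scope `"intersection"`); `"union"`/`"either"` and `"all"`
  are available since the set of modules entering a published correlation
  is rarely recoverable from a figure legend. Fraction-positive values
  are computed per result over that result's significant modules.
* Network nodes are gene sets with their qualifying (comparison,
  direction) memberships attached — required for the recurrence rule —
  and the automated grouping unit is the connected component; naming
  clusters is left to the user.

## Problem sizes

The test suite and the acceptance script exercise the pipeline at
2,000 genes x 200 modules (50 nonzero weights each) with 100
permutations for calibration, recovery and concordance experiments
(200, 100 and 50 seeded replicates respectively), and one full-scale run
at 18,952 probes collapsed to 13,801 genes x 850 modules x 100
permutations x 6 comparisons — the dimensions of a realistic compendium
library. These sizes keep every experiment deterministic and fast on a
single CPU while leaving the statistical behavior of the full-scale
geometry visible.

## Known limitations

* The permutation null destroys gene-gene correlation; on real data with
  correlated expression noise the null is anti-conservative to a degree
  the synthetic tests cannot measure.
* With 100 permutations, $\hat\sigma$ has appreciable estimation noise,
  which inflates the tail fraction of $|z| \ge 3$ above the idealized
  normal value $2\Phi(-3) \approx 0.0027$; calibration tests therefore
  check an interval, not a point.
* The projection treats modules one at a time; overlapping modules are
  scored marginally, with no joint model.
* Probe collapsing by unweighted averaging is the convention adopted
  here; expression-weighted alternatives are not implemented.
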