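---
title: "Methods: coexpression-network analysis of a CIE drinking study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coexpression-network analysis of a CIE drinking study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cienet)
```

This vignette is the package's account of its statistical machinery: the
study design it models, the synthetic-data generator that stands in for the
microarrays, each analysis stage's model and defaults, the numerical choices
that were genuinely open, and what the parameter-recovery tests do and do
not demonstrate about real data.

## The study design being modeled

The package analyses a 2×2 design crossed from ethanol **vapor** exposure
(CIE vs Air) and voluntary **drinking** (2-bottle choice vs water only),
giving four treatment groups — CIE Drinking, Air Drinking, CIE NonDrinking,
Air NonDrinking — of about 12 mice each, one expression array per mouse.
Drinking mice log six baseline weeks of five daily limited-access sessions,
then four cycles of vapor (or air) exposure each followed by five more
drinking days. The phenotype of interest is the escalation of intake in the
CIE-Drinking group across cycles; the genomic questions are which probesets
respond to which exposure combination, which coexpression modules track
drinking, and which modules lose their internal wiring under CIE drinking.

## The synthetic-data generator

`sim_config()` / `simulate_drinking()` / `simulate_expression()` generate
the whole study from one seed.

**Drinking.** Daily intake is phase mean plus i.i.d. Gaussian noise
truncated at zero (intake is a consumed mass). Phase means are
`baseline_mean` (default 2.2 g/kg per 2-h session, a typical limited-access
level for C57BL/6J mice) plus per-cycle escalations: the CIE-Drinking
default `c(0.7, 0.3, 1.0, 1.3)` g/kg reproduces the qualitative trajectory
of the modeled experiment — a jump after cycle 1, a dip at cycle 2, then
strong escalation — while Air-Drinking rises modestly
(`c(0.3, 0.3, 0.4, 0.4)`). Per-mouse baseline and CIE-response random
effects (SD 0.3 g/kg each) give animals stable individual differences, which
is what makes mouse-level trait correlations meaningful. NonDrinking mice
are identically zero.

**Expression.** Gene $g$ in module $q$ follows
$x_{gs} = \mu_g + \lambda_g f_q(s) + \delta_g\,[\text{group}(s) \in A] +
\varepsilon_{gs}$, with $\mu_g \sim N(8, 0.5^2)$ on the log2 scale,
loadings $\lambda_g$ uniform on `loading_range` and factors standardized
across the pooled sample set. Background genes are pure noise. Defaults:

* `loading_range = c(0.2, 0.95)` — a hub-periphery spread. Real modules have
  strongly and weakly connected members; a narrow loading band produces
  modules whose genes are statistically interchangeable, and then
  *connectivity* (as opposed to membership) carries no recoverable signal at
  n = 12 per group. The spread is what makes the disruption statistic
  testable at the study's group sizes.
* `noise_sd = 0.5` — residual log2 SD typical of RMA-summarized arrays.
* `module_group_effect = 2` — each non-trait-linked module's factor receives
  a mean offset in one treatment group (rotating across groups by module
  index). The modeled study selected its network universe by one-way ANOVA,
  so its modules are by construction treatment-responsive; the offset makes
  the planted modules survive the same filter.

**Trait linkage.** A trait-linked module's factor is a monotone blend
$f = a\,s(\text{trait}) + \sqrt{1-a^2}\,z$ of the normal scores of the
cycle-4 change-from-baseline trait and independent noise. The weight $a$ is
calibrated by Monte Carlo (pre-drawn noise matrix, root-finding on the
expected sample Spearman) so the population Spearman correlation equals the
configured target; an analytic conversion is unavailable because half the
trait vector is tied at zero (NonDrinking animals carry trait 0 so that
trait vectors span all samples). Cycle-4 change is the linked trait because
it is the strongest behavioral readout of CIE escalation.

**Disruption.** For a disrupted module, within the designated group only,
the designated fraction of member genes exchanges its shared-factor term for
an independently re-drawn loading on an independent per-gene factor. Simply
re-drawing the loading's sign or magnitude on the *same* factor would leave
$|\mathrm{cor}|$ — and hence an unsigned network — unchanged; replacing the
factor is what actually severs the gene from its module in that group while
leaving the other groups untouched.

**DE effects.** `n_de_genes` background genes get a `de_effect` (default
1.0 log2) mean shift in `de_group` (default CIE Drinking). The modeled
study reports no effect sizes, so this default is chosen for testability,
not fidelity.

## Differential expression

`pairwise_contrasts()` fits one four-group linear model per probeset
(residual variance pooled across all four groups, df = n − 4) and tests all
six pairwise differences, labeled C1–C6 with C1 = CIE Drinking vs Air
Drinking, C2 = CIE NonDrinking vs Air NonDrinking, C3 = CIE Drinking vs CIE
NonDrinking, C4 = CIE Drinking vs Air NonDrinking, C5 = CIE NonDrinking vs
Air Drinking, C6 = Air Drinking vs Air NonDrinking. BH FDR is applied
within each contrast, matching per-comparison significance counting.
Zero-variance probesets are flagged and assigned p = 1 rather than dropped.
Empirical-Bayes variance moderation is available behind `moderate = TRUE`
(via `limma::squeezeVar`); the default is the plain pooled-variance t, whose
contracts (type-I calibration, transitivity of log-ratios) hold without any
shrinkage assumptions. `two_factor_model()` fits the 2×2 with interaction on
sum-to-zero coding, so its coefficient tests are Type III tests on the
balanced-coded design.

## Preprocessing

`quantile_normalize()` maps every column onto the row-wise mean of the
sorted columns; ties receive the mean of the reference values at their rank
positions, which makes the transform idempotent. `anova_filter()` selects
the network universe at one-way-ANOVA BH-FDR ≤ 0.01; `union_filter()`
merges per-region selections. Batch correction is deliberately a hook: the
pipeline ingests an already batch-corrected matrix, and the generator plants
no batch structure by default.

## Network construction and module detection

`adjacency()` is unsigned by default, $a_{ij} = |\mathrm{cor}(x_i,
x_j)|^\beta$ (signed option available), with $\beta$ either fixed (6 is the
study convention; 8 for one region) or chosen by `pick_soft_threshold()`
as the smallest power whose signed scale-free fit $R^2$ reaches 0.80.
`topological_overlap()` folds shared-neighbor structure into the pairwise
similarity; `1 − TOM` is the clustering dissimilarity.

`detect_modules()` is a native adaptive tree-cut with three stages:

1. **Cut.** Average-linkage clustering of `1 − TOM`, cut at a quantile of
   the merge heights indexed by `deep_split` (0→0.99, 1→0.96, 2→0.92,
   3→0.85). Cutting at a height *quantile* rather than a fixed
   dissimilarity adapts the cut to the dendrogram's scale: soft-thresholded
   dissimilarities compress all structure into a thin band near 1, and no
   fixed cut height works across powers and sample sizes.
2. **Core refinement.** Average linkage chains weakly attached genes onto
   real branches. Each candidate branch (≥ `min_module_size`) is pruned by
   iteratively dropping genes whose mean TOM to the branch falls below half
   the branch median; a surviving core must also be at least 3× better
   connected within than to the rest of the network (this coherence ratio is
   what kills clusters assembled from pure noise). Cores that are fragments
   of one module (cross-core mean TOM ≥ 40% of the smaller within-core mean)
   are re-merged.
3. **Assignment.** Every gene joins the best-scoring core it qualifies for,
   with a laxer threshold (25% of the core's median member score) than the
   core pruning used — this re-admits genuinely weakly loaded members that
   the pruning stage holds out. Genes qualifying nowhere are "grey".

`min_module_size` defaults to 30, consistent with the smallest modules the
modeled study reports (~33 probesets). Exact equivalence with the reference
dynamic hybrid tree-cut is *not* claimed; the test surface is parameter
recovery (adjusted Rand index against planted memberships), not label
identity. Deep-split 0 on data whose modules are weak can produce degenerate
coarse cuts — the modeled study itself chose deep split per region by eye,
and `deep_split` is correspondingly a required analyst input here. No
eigengene merging is applied by default (`merge_height` is available).

`module_eigengenes()` returns the first principal component of each
module's gene-standardized submatrix, sign-oriented to correlate positively
with the module's mean profile; `connectivity_stats()` reports kTotal, kIM
and kME per gene.

## Module validation

`validate_modules()` compares each module's mean off-diagonal TOM with 100
same-size gene sets drawn uniformly without replacement from the whole
network universe (grey included — random draws are meant to be arbitrary).
Z scores get one-sided upper-tail normal p-values (an empirical-rank option
exists), BH-corrected across the module set; FDR ≤ 0.2 validates. The grey
module is reported with FDR pinned at 1. The normal approximation is
accurate at realistic scale: on a ~1,000-gene network the null Z over random
pseudo-modules is standard normal to KS distance < 0.03, while on very
small networks (a few hundred genes) the mean-TOM statistic retains visible
right skew.

## Trait correlation

`correlate_eigengenes()` / `correlate_genes()` use Spearman rank correlation
with average ranks for ties and the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ (exact permutation p available for
n ≤ 10). All samples enter by default, NonDrinking animals carrying trait
value 0: the very small module-trait p-values only arise at the full-sample
n, implying non-drinkers were included in the modeled analysis; exclusion is
an option (`include_nondrinkers = FALSE`). Percent-change traits are
undefined (flagged `NA`) for animals with zero baseline, which is why the
cycle-4 *absolute* change is the package's default summary trait.

## Module disruption

`disruption_z()` compares, per module, the correlation over member genes of
intramodular connectivity computed separately in two treatment groups
(canonically CIE Drinking vs Air NonDrinking) against a null built from 200
sample subsets drawn without regard to group labels, each of the smaller
group's size, without replacement. `Z = (obs − μ)/σ` with μ, σ taken over
pairwise correlations between bootstrap networks; modules with
`Z_cor.kIM ≤ −2` are called disrupted. Three design choices were genuinely
open and are resolved as follows:

* **Disjoint null pairs** (`pair_mode = "disjoint"`, default). The observed
  statistic compares two disjoint sample sets, but two random 12-of-48
  subsets share on average three samples, and shared samples share sampling
  noise — with all pairs admitted the null correlations are inflated and
  every module drifts toward "disrupted" (we observed all-module Z ≈ −1.3
  under no disruption). Restricting the null to fully disjoint bootstrap
  pairs (~370 of the ~20k pairs at these sizes) matches the null to the
  observed statistic's sampling structure and re-centers null modules at
  Z ≈ 0. `pair_mode = "all"` retains the literal reading.
* **Rank correlation of connectivities** (`cor_method = "spearman"`,
  default). Power-β connectivities are extremely heavy-tailed, so Pearson
  correlation is dominated by a handful of hubs; with 80% of a module
  scrambled, the intact hubs alone can hold Pearson concordance up and mask
  the disruption. Spearman weighs every member gene; in replicate
  experiments it flags the scrambled module essentially always, where
  Pearson misses borderline cases. Pearson remains available.
* **kME reading** (`kme_mode`). The modeled analysis glosses kME as "total
  connectivity" while the symbol conventionally denotes eigengene-based
  module membership; both readings are implemented (`"eigengene"` default,
  `"ktotal"` option), and the headline flag uses kIM in either case.

The bootstrap null is label-blind, so the statistic is only calibrated when
the two groups are exchangeable under the null. Group-specific *mean*
structure (e.g., a module whose factor is shifted in one group) reduces
that group's within-group factor variance relative to label-mixed subsets
and biases Z negative for reasons unrelated to wiring. The disruption
parameter-recovery experiments therefore plant modules without group mean
offsets; on real data the same caveat applies — a strongly DE module can
show a negative Z without a true connectivity change.

## Enrichment

`hypergeom_overlap()` is the exact upper-tail hypergeometric test;
`module_list_enrichment()` runs all module × list tests, corrected across
the whole table — BH at FDR ≤ 0.05 for module/list comparisons, Bonferroni
≤ 0.05 by convention for cell-type marker lists. The default universe is
the network input set (enrichment conditions on what could have been
assigned); the full-array universe is a configuration away.

## Pipeline, seeds, determinism

`run_pipeline()` chains the stages, writing one self-describing TSV per
stage plus a combined per-module summary (disrupted at Z_cor.kIM ≤ −2;
cycle-4 trait correlation p < 0.01; DE over-representation FDR < 0.01). All
randomness derives from one master seed through fixed per-stage offsets
(`derive_seed()`), and reruns are byte-identical.

## Problem sizes used by the test suite

The parameter-recovery suite runs at the study's sample scale (48 arrays)
with gene counts chosen for sharp, fast checks: module recovery on 2,000
genes with five planted 100-gene modules (loadings 0.5–0.9); validation
nulls with 100 permutations and 200 random pseudo-modules of the planted
size; disruption recovery over 20 seeded replicates of the default
generator with one module 80%-scrambled; type-I calibration on 10,000 null
probesets. These sizes are the package's chosen experimental conditions and
are fixed in the tests.

## Limitations

The generator emulates group structure, module coexpression, trait linkage
and connectivity disruption, but not probe-level artifacts, batch effects,
correlated background, heteroscedastic genes, or multiple brain regions
with shared biology (a region is one independent dataset). Passing
recovery tests therefore demonstrates the estimators' correctness and
calibration under the stated generative model, not their robustness to
real-array pathologies — those are the province of the upstream QC and
batch-correction steps the pipeline deliberately leaves to established
tools.
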