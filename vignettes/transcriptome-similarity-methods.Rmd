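---
title: "Methods: scoring cell-model transcriptome similarity with non-DEGs and DTU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring cell-model transcriptome similarity with non-DEGs and DTU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txsim)
```

## The problem and the design

`txsim` compares the baseline transcriptome of an in vitro cell model
against a reference tissue measured in many donors (the *control* group,
typically ~24 samples) using a small number of model replicates (the *test*
group, typically 3). The design is deliberately asymmetric: the reference
captures inter-individual biological variability, the model contributes a
handful of technical/biological replicates. Two complementary similarity
readouts are computed per comparison:

1. **non-DEGs** — genes a negative-binomial Wald test cannot distinguish
   between the groups, among genes expressed above a noise floor. More
   non-DEGs means the model preserves more of the reference transcriptome.
2. **non-DEGs^DTU−** — the same set after removing genes whose *isoform
   composition* shifted significantly even though total expression did not.
   Gene-level counts sum over transcripts, so a switch from the dominant
   isoform to alternatives is invisible at the gene level while potentially
   changing the protein product; such genes should not count as "similar".

Each cell model and time point is one independent comparison: size factors,
dispersions and tests are all estimated within that comparison only.

## The DE engine and its assumptions

The engine is a compact reimplementation of the standard bulk RNA-seq
pipeline, built so that the downstream decision logic (thresholding
adjusted p-values and baseMean) is fully reproducible and testable:

* **Size factors**: median-of-ratios. For sample $j$,
  $s_j = \operatorname{median}_g\, K_{gj} / (\prod_{j'} K_{gj'})^{1/m}$,
  restricted to genes positive in every sample. The median is taken on the
  natural ratio scale (the definition), which coincides with the log-scale
  median whenever the reference gene count is odd. If no gene is positive
  in all samples the estimator is undefined and the function says so; the
  orchestrator then falls back to gene-level size factors for the isoform
  matrix (the only place this arises in practice).
* **Dispersions**: per-gene method of moments on normalized counts within
  each group, pooled by residual degrees of freedom
  ($\hat\alpha_g = (\widehat{\mathrm{Var}} - \hat\mu\,\overline{1/s})/\hat\mu^2$),
  then shrunk in log space toward a trend $\alpha(\mu) = a_0 + a_1/\mu$
  fitted to binned medians of the gene-wise estimates. The shrinkage weight
  is residual df versus `prior_df = 10` pseudo-observations. Binned medians
  (rather than a gamma GLM on positive estimates only) keep the trend
  unbiased when data are near-Poisson, where half the moment estimates are
  negative. There is no Cox–Reid adjustment, no outlier refitting and no
  independent filtering: a documented numerical divergence from
  full-featured DE packages, accepted because the pipeline's outputs are
  *sets* defined by thresholds, and calibration is verified directly by
  simulation (null p-value uniformity, false-call rates).
* **Wald test**: group means on the normalized scale are fitted by Fisher
  scoring on $\eta = \log m$ (score $\sum_j (y_j - \mu_j)/(1+\alpha\mu_j)$,
  expected information $\sum_j \mu_j/(1+\alpha\mu_j)$), initialized at the
  ratio of group totals, steps clamped to $\pm 5$, convergence at
  $|\Delta\eta| < 10^{-12}$, 100 iterations maximum. The two groups factor
  independently, so $\mathrm{Var}(\hat\beta) = I_c^{-1} + I_t^{-1}$ and
  $z = \hat\beta/\mathrm{se}$ against a standard normal.
* **Degenerate genes**: all-zero genes are excluded (`NA` p and padj, not
  counted in the BH denominator). A gene zero in exactly one group gets a
  half-count floor in that group for the test statistic, and its reported
  `log2FoldChange` uses pseudo-counted (+0.5) normalized group means so
  volcano coordinates stay finite; the two uses are deliberately separate
  so the pseudo-count never leaks into inference.
* **BH adjustment** delegates to `stats::p.adjust(method = "BH")`; the test
  suite checks it against an independently coded step-up oracle.

## Thresholds and their defaults

| parameter | default | unit | role |
|---|---|---|---|
| `alpha_de` | 0.05 | adjusted p | non-DEG (`padj > alpha`) / DEG (`padj < alpha`) split |
| `basemean_min` | 10 | normalized counts | expression floor for both sets (strict `>`) |
| `lfc_flag` | 1 | log2 fold change | direction annotation only, never membership |
| `cpm_floor` | 1 | counts per million | isoform low-expression filter (strict `<` removes) |
| `delta_pct` | 10 | usage percentage points | similar-usage filter (inclusive `<=` removes) |
| `max_missing_frac` | 0.2 | fraction of samples | detection filter (strict `>` removes) |
| `small_n` | 5 | samples | below this, a group must detect the isoform in all samples |
| `alpha_dtu` | 0.01 | raw ANOVA p | DTU call on the dominant isoform |
| `k_replicates` | 3 | replicates | bootstrap subset size |

Boundary semantics are deliberate and tested: a gene exactly at
`padj = 0.05` or `baseMean = 10` is in *neither* set; an isoform with a
usage difference of exactly 10 points is removed; one with mean CPM exactly
1 is kept. The DTU threshold is stricter than the gene-level one and applied
to raw p-values without multiplicity adjustment, because isoform-level
quantification carries a higher intrinsic false-positive rate and the call
is confined to one pre-specified isoform per gene (the control-dominant
one).

## The DTU cascade: order, synchronization, conventions

Filters run in a fixed order — low expression (on counts), similar usage
(on percentages), detection (on percentages) — each on the previous step's
survivors, so the audit trail attributes every removal to the first rule
that fires and the removal sets are disjoint. The count and percentage
views are then synchronized (an isoform removed from one view is removed
from the other) and genes left with a single isoform are pruned, since
usage shifts are undefined for one isoform.

Decisions made where the procedure was genuinely open:

* **CPM basis**: group-mean CPM is computed on *normalized* isoform counts
  against per-sample library sizes (column sums by default), and the filter
  fires when *either* group is below the floor — an isoform invisible in
  one dataset cannot be compared. Exposed via `cpm_floor` / `lib_size`.
* **"Detected"** means usage percentage strictly above zero (equivalently,
  a positive count).
* **No renormalization**: usage percentages are never recomputed after
  removals. Renormalizing would silently change the similar-usage filter's
  semantics and make the ANOVA depend on which other isoforms were removed.
* **ANOVA**: classical equal-variance one-way fixed-effects ANOVA on usage
  percentages (percentages are approximately linear, unlike counts), via
  `stats::oneway.test(var.equal = TRUE)`; with two groups the F statistic
  is exactly the squared pooled t statistic, which the tests exploit as an
  oracle. Zero within-group variance in both groups is resolved by the
  limit convention: p = 1 for equal means, p = 0 otherwise.
* **DTU call**: keyed to the control-dominant isoform's p-value only. A
  significant *minor* isoform never flags the gene; a column reports when
  the test group's dominant isoform identity differs from the control's,
  for inspection. Dominance ties break lexicographically by isoform id.

## Bootstrap replicate selection

All $\binom{n}{k}$ subsets of a model's replicates are evaluated against
the full control group; each subset is a fresh comparison (size factors and
dispersions re-estimated). The criterion is the **non-DEG count** (the DEG
count is reported alongside; the two rankings coincide only when the tested
gene universes match, which is why non-DEGs are authoritative). Ties break
to the lexicographically smallest sorted replicate tuple, making the result
invariant to input order. A model with $k-1$ replicates may proceed with
all of them behind an explicit flag (`allow_fewer_replicates`), mirroring
panels where one replicate is lost to sequencing-depth filtering. The full
control group is always used.

## Pathway coverage

Gene mode divides the hit count by the pathway size; node mode divides
covered protein nodes by the node count, because mapping tools frequently
assign several genes to one protein node. Node coverage therefore dominates
gene coverage, and DEG and non-DEG coverages of the same pathway can sum
above 100 — the package ships a constructed fixture demonstrating this
non-complementarity. Gene mode is the default; the package takes any GMT
and never fetches pathway databases (versioned external content). The
shipped `liver_pathways_synthetic.gmt` is a synthetic 20-pathway stand-in
whose member lists are draws over the simulator's gene ids, usable for
tests and the analysis scripts only.

Ensembl-style id versions are kept verbatim by default;
`strip_id_version = TRUE` strips them for pathway mapping when needed.

## QC diagnostics

Pairwise Spearman correlation (average-rank ties) of normalized counts,
with constant columns reported as missing. The per-model **variation
coefficient** is `100 * sd / mean` (sample sd) of the correlations between
the model's replicates and all control samples — the basis is a documented
interpretation choice (`basis = "intra"` switches to within-model pairs)
and is never compared against any external value.

## What the simulator emulates — and what it does not

`simulate_experiment()` draws: log-uniform library sizes (20–40 M reads);
lognormal relative expression (sdlog 1.5); NB gene counts with
$\alpha(\mu) = 0.05 + 2/\mu$; 1–5 isoforms per gene with Dirichlet(2) usage;
DE genes (default 30%) with $N(0, 2)$ log2 fold changes truncated to
$|{\rm lfc}| \ge 1$; DTU genes (default 10% of genes, drawn among
multi-isoform genes, disjoint from DE genes) whose control-dominant isoform
loses 30 usage points in the test group, redistributed proportionally.
Isoform counts are a multinomial split of the gene count, so gene totals
equal isoform sums exactly — the construction that lets a gene be non-DE
yet DTU. Defaults mirror the emulated study design: 24 control vs 3 test
samples and 2000 genes, a problem size chosen so the whole test suite and
the analysis scripts run in minutes on a laptop while keeping thousands of
genes per calibration check.

Not emulated: per-sample biological variation of usage *within* a group
(usage varies only through multinomial sampling), correlated genes,
GC/length bias, batch effects, and donor structure in the reference. Null
isoforms therefore have very tight usage at realistic depths, which makes
the similar-usage filter highly effective on simulated nulls; passing
calibration here shows the machinery is correct, not that real-data DTU
lists will be this clean. Conversely the planted-signal checks (recall/FDR
of DE and DTU calls, exhaustive bootstrap verification) exercise exactly
the decision logic applied to real data.

## Known limitations

* The DE engine's p-values will not numerically match a full-featured
  package on real data (no Cox–Reid, no outlier handling); set-level
  decisions at the stated thresholds are the supported output.
* With 2–3 test replicates, dispersion information comes mostly from the
  control group; strongly heteroskedastic models are shrunk toward the
  reference trend.
* The variation-coefficient definition is an interpretation (see above).
* Pathway coverage treats gene sets as flat membership lists; no topology.
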