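---
title: "Whole-genome average-similarity phylogenies: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-genome average-similarity phylogenies: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avephylo)
```

## The model

`avephylo` estimates evolutionary distances between whole genomes from
the E-values of best-matched protein pairs. The underlying assumption is
that, averaged over thousands of genes, sequence similarity between two
proteomes decays with divergence time even though individual genes are
noisy witnesses (lateral transfer, unequal rates, loss). Averaging over
*all* best matches — rather than a curated ortholog subset — is the point:
no gene is excluded for being phylogenetically discordant, so the
distance reflects the genome as a whole.

For an ordered pair (X, Y), each query gene of X contributes a point
whose x-coordinate is the log10 E-value of its best match in X's own
proteome (a proxy for query length/composition: self-matches are exact,
so their E-value mainly tracks alignment length) and whose y-coordinate
is the log10 E-value of its best match in Y. The self coordinate acts as
a per-gene normaliser: dividing the shifted averages,

$$ m = \frac{\mathrm{AvE}_Y - C_{OV}}{\mathrm{AvE}_X - C_{OV}}, $$

measures how far the cross-match cloud has drifted from the diagonal
(identical genomes, m = 1) toward the cut-off line (no detectable
similarity, m = 0). Shifting by the cut-off $C_{OV}$ places the
no-signal corner at the origin, so m is the slope of the average point
through the origin. Because averaging happens *before* the ratio, short
proteins are not over-weighted the way per-gene score ratios would
over-weight them.

The dissimilarity statistic is $\tan\theta$, $\theta$ being the angle
between the pair's line (slope m) and the diagonal. The statistic is
asymmetric — $\tan\theta_{XY} \neq \tan\theta_{YX}$ in general, because
the two proteomes differ in gene content — and both orientations are kept
until the final distance combination.

### The tan θ convention

For two lines of slopes $m$ and $1$ through the origin the exact tangent
of the angle between them is $(1-m)/(1+m)$. The simple complement
$1-m$ has the same endpoints (0 at $m=1$, 1 at $m=0$) and is a monotone
re-parameterisation. Both are implemented (`convention = "angle"`
(default) or `"complement"`); since the calibration below is refit per
convention, the choice is absorbed by the regression and downstream
trees are insensitive to it. The default is the geometric formula because
θ is *defined* as an angle.

### Calibration against 16S rDNA

tan θ is not linear in time. It is calibrated against the 16S rDNA
substitution rate S — the percentage of substituted sites among aligned
columns, excluding any column with a gap or ambiguity code in either
sequence (`substitution_rate()`). All (tan θ, S) points are used,
including duplicates from multiple 16S copies per genome and both
orientations of each pair; asymmetry is treated as informative scatter
rather than averaged away.

The regression family is exponential. Two forms are provided:

* `exp_minus_one` (default): $S = c_1 (e^{c_2 \tan\theta} - 1)$, which
  forces $S(0) = 0$ — identical genomes must have zero distance;
* `exp`: $S = c_1 e^{c_2 \tan\theta}$, kept for sensitivity analysis.

Fitting is nonlinear least squares on the untransformed S scale
(`minpack.lm::nlsLM`), initialised at $c_1 = \max(S)/e$, $c_2 = 1$ —
a starting curve inside the data's range, which converges reliably at
the few-thousand-point scale of real calibrations. $R^2$ is reported as
$1 - SS_{res}/SS_{tot}$ on the same untransformed scale. A preset
(`calibration_preset("satoh2013")`) carries the published constants
(const1 = 5.0112, const2 = 2.2223, R² = 0.9366) for users without their
own 16S panel; it is recorded under the `angle` convention and the
`exp_minus_one` form, so users of other settings should refit.

### The F distance family

Applying the calibration to the two orientations gives $F_{XY}$ and
$F_{YX}$; the symmetric indices are the mean ($F_{AV}$), the higher
($F_H$) and the lower ($F_L$) of the two. $F_{AV}$ is the default tree
distance: the gene-reduction experiment (below) shows it is the only one
of the five whose topology is robust to strongly unequal gene content.
For the oriented "indices" $F_{XY}$/$F_{YX}$ a symmetric matrix is still
required by NJ; orientation is fixed by label order (the
lexicographically earlier taxon of each pair is the query) and the one
value fills both cells.

## Trees

Neighbor-joining (Saitou–Nei, via `ape::nj`) builds the tree; on an
additive matrix it returns the generating topology and branch lengths
exactly, which is the package's acceptance oracle. Negative branch-length
estimates, which NJ can produce on non-additive input, are clamped to
zero with the deficit moved to the adjacent parent edge (standard
practice; warned about, never silent). 16S reference trees use the
Jukes–Cantor correction $d = -\tfrac34\ln(1-\tfrac43 p)$ with pairwise
gap/ambiguity deletion; $p \ge 0.75$ is refused as saturated rather than
returned as infinity.

Bootstrap support does not resample alignment columns (there is no
alignment); it resamples the method's own sampling unit, the
(query-gene, E-value) point. Per replicate and per ordered pair, k points
are drawn with replacement from that pair's point set, and the whole
tan θ → F → matrix → NJ chain is recomputed. Resampling is per ordered
pair — a single global pool would leave matrix entries undefined whenever
a pair contributed no draw. Replicate r seeds its generator at
`seed + r`, so any single replicate is reproducible in isolation.
Consensus is strict majority (> 50%, ties excluded), matching the
classic majority-rule default; supports are occurrence counts (with
percentages via `support_table()`).

The gene-reduction experiment emulates sequencing/annotation asymmetry:
one taxon's gene set is subsampled without replacement (default 10%),
all best-match tables involving that taxon are rebuilt, and trees are
re-inferred R times per index. It operates on best-match tables, the
pipeline's native currency: query-side records of removed genes are
dropped, and records whose best *match* was removed are dropped rather
than re-searched (re-running the similarity search on the reduced
database is out of scope; on the synthetic fixtures, where best-hit
geometry is generated directly, the two procedures coincide).

## The synthetic generator

`gen_best_hit_tables()` synthesises the E-value geometry directly instead
of emulating a search engine: self log-E values are uniform on
[−180, −5], mirroring the observed length-driven spread of self-match
E-values, and the cross value for gene i is
$y_i = C_{OV} + m\,(x_i - C_{OV}) + \varepsilon$, clipped to
$[-180, C_{OV}]$. With $\varepsilon = 0$ every point lies exactly on the
slope-m line, so the recomputed slope equals the target for *any* subset
of points — which is what makes the noiseless fixtures exact oracles for
the bootstrap (all resamples reproduce the point estimate) and the
gene-reduction experiment (any subsample preserves every pairwise
distance). `gen_tables_from_tree()` derives per-pair target slopes from
a tree's path lengths through the inverse calibration, giving end-to-end
fixtures whose correct answer is known by construction.

What the generator does **not** emulate: gene duplication and loss,
lateral transfer, length-dependent E-value structure beyond the uniform
self spread, database-size effects on E-values, and genuinely asymmetric
gene content (target slopes are symmetric unless specified otherwise).
Passing the package's tests therefore demonstrates that the *estimator
chain* is correct — preprocessing, slope, calibration, distances, NJ,
bootstrap — not that the method resolves any particular real clade;
robustness claims on real genomes rest on the original study design, not
on these fixtures.

## Numerical and degenerate-input choices

* E-value 0 → log value −180; all log values floored at −180.
* The cut-off (raw E = 10 by default) is also an admission filter: hits
  above it are discarded before best-hit selection.
* Ties at the minimum E-value keep the first row in input order, the
  order search tools emit; deterministic for fixed input.
* Genes with no admissible cross match contribute no point; n counts
  plotted points only.
* A pair with zero shared points gets the calibration's value at
  tan θ = 1 (the no-similarity ceiling) with a warning, so one empty
  pair cannot abort a whole-matrix run.
* m is clamped to [0, 1]; sampling noise can push AvE_Y marginally past
  AvE_X for near-identical genomes. Excursions beyond 1e−9 warn.
* PHYLIP matrix names are padded/truncated to 10 characters with a
  collision check; a sidecar `.labels` file preserves full names.
* Trees are built unrooted; rooting at a declared out-group is a display
  step (`root_at_outgroup()`).

## Problem sizes

The test suite and bootstrap checks run at deliberately compact scale:
8-taxon trees with 300 genes per taxon for the end-to-end and
gene-reduction fixtures (10% reduction keeps 30 genes), B = 100
replicates with k = 1000 resampled points for the full-support check,
5,000 pairs for calibration-recovery under 10% multiplicative noise, and
200 random 5–12-leaf additive matrices for the NJ oracle. These sizes
keep the suite fast while leaving each check's statistical content
intact; all generators accept larger values.

## Known limitations

* The calibration preset is only as good as its 16S panel; distances
  beyond the calibrated range (tan θ → 1) compress against the
  exponential's ceiling, so deep branches saturate.
* F distances are not corrected for rate heterogeneity (no gamma, no
  LogDet); the method inherits NJ's sensitivity to strong non-additivity.
* The reciprocal-best-hit variant discards genes aggressively and is
  provided for comparison, not recommended as the default.
* Fitch–Margoliash estimation is not implemented; additivity is instead
  checked via NJ recovery and cophenetic correlation on synthetic
  matrices.
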