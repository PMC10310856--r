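---
title: "Network propagation, disease modules and astrocyte morphometrics with glianet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network propagation, disease modules and astrocyte morphometrics with glianet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glianet)
```

## Overview

glianet implements a two-part analysis framework for linking disease
genetics to cell-level phenotypes in glia. The network half takes GWAS
association hits for a trait, diffuses them over a composite
protein-interaction network, and extracts *disease modules*: communities
of interacting genes whose propagation scores are collectively elevated.
Downstream tools compare module catalogs across diseases, test gene-set
enrichment, benchmark the propagation ranking against gold-standard gene
sets, and intersect three network expansions (GWAS, transcriptome,
proteome) to nominate sign-concordant multi-omics candidate genes. The
morphometrics half implements the quantitative cell-shape and trafficking
statistics used to phenotype astrocyte processes: form factor,
distance-binned particle-density profiles, volume ratios, percent area
overlap, orientation dispersion and track speeds.

Every stage can be exercised without external data through the
synthetic-data generators, which attach machine-readable ground truth to
their outputs.

## The network model

### Interactome construction

`build_interactome()` merges edge tables from scored databases (STRING-like
combined scores in $[0,1]$) and unscored ones (BioGRID/IntAct-like). Edges
from scored tables must exceed the confidence threshold *strictly*
(default 0.75); unscored tables pass all edges, since a confidence filter
only applies where a confidence exists. The merged graph is undirected and
simple: self-loops are removed, duplicate pairs collapse to one edge, and
when duplicates disagree on score the maximum is kept before thresholding
(the most permissive reading of a "combined" score). Gene identifiers are
treated as opaque strings, upper-cased and whitespace-stripped; identifier
mapping across naming systems is out of scope.

### Seed weights

`load_seed_weights()` turns a trait's association table into nonnegative
starting weights $w_g = -\log_{10} p_g$. Several rows for one gene (within
a trait or across pooled traits, e.g. a general and a sporadic form of the
same disease) keep the largest weight, i.e. the most significant
association. A p-value of exactly 1 is a legal boundary giving weight 0.

### Personalized PageRank

`personalized_pagerank()` computes the stationary distribution of a random
walk that, with probability $1-d$, restarts at a seed gene drawn
proportionally to its weight:

$$x = (1-d)\,p + d\,W x,$$

with $p$ the seed weights normalized to sum one and $W$ the
column-stochastic adjacency matrix. We solve by sparse power iteration to
an L1 tolerance of $10^{-12}$ (contraction factor $d$ guarantees geometric
convergence; non-convergence within the iteration cap raises an error that
reports the residual). Mass on degree-zero nodes is redistributed through
$p$, the standard dangling-node convention. The damping factor is not
dictated by the method; we default to the conventional $d = 0.85$ and
expose it. The test suite checks the iterative solution against a dense
linear solve to $10^{-10}$ and against an independent PageRank
implementation.

The per-gene scores are probabilities (they sum to 1); only their ranking
matters downstream, and the selection step is invariant to monotone
transforms of the scores.

### Top-fraction selection

`select_top_fraction()` keeps the $\lceil f N \rceil$ highest-scoring
nodes (default $f = 0.25$, the upper quartile of the ranking). Ceiling
keeps the selection non-empty for any positive fraction; ties at the
cutoff break lexicographically by gene identifier so runs are
deterministic.

### Iterative walktrap and module size rules

`iterative_walktrap()` applies walktrap community detection (random-walk
length 4, the algorithm's canonical default, exposed as `steps`) to the
subgraph induced by the selected nodes. Any community larger than
`max_size` (default 300) is re-clustered on its induced subgraph,
recursively, until every community respects the ceiling. A community that
walktrap returns whole is flagged *unsplittable* and kept, with a warning,
rather than discarded — no genes silently vanish. Disconnected inputs are
decomposed first; isolated vertices become singleton communities. The
final communities partition the clustered node set. Communities must
*exceed* `min_size` (default 10) to be reported as modules.

### Module significance

`ks_module_significance()` compares each module's member scores with the
scores of all other genes in the background universe using a two-sample
Kolmogorov–Smirnov test, one-sided in the direction "member scores
stochastically greater" — a disease module is one enriched in high
propagation scores. (In R's CDF-based convention this is
`ks.test(member, background, alternative = "less")`; the package handles
the translation, and the exact small-sample p-value is used where
available.) P-values are Benjamini–Hochberg-adjusted across the modules of
one trait's run, and modules with adjusted $p < 0.05$ are flagged
significant.

The choice of background matters. The default (`background = "selected"`)
compares a module against the other genes of the selected subgraph —
the universe on which clustering operates. Because selection already
conditions on high scores, this is the conservative choice: under a
structureless null with uniformly spread seeds the measured rate of
significant modules is about 0.04 at $\alpha = 0.05$ (the test suite
bounds it at 0.07 over 200 replicates). Comparing against all scored
genes (`background = "all"`) is available as a switch but is
anti-conservative for exactly that reason: every subset of the top
quartile outranks the full score distribution.

A practical consequence, visible in the synthetic experiments: the
selected-background test only has contrast when the selected subgraph is
substantially larger than any single seeded neighbourhood. With a
synthetic interactome of 10 planted blocks of 100 genes and all seed mass
in one block, the selected quartile (250 genes) contains the block plus
150 genuinely lower-scoring genes, and the block is recovered as
significant modules covering it almost exactly (Jaccard ≥ 0.9 in every
prototyping run; the acceptance suite requires ≥ 0.5 in ≥ 95 of 100
replicates). When the selected set is barely larger than the seeded block
itself, the block's sub-modules become each other's background and power
drops — a regime a practitioner should avoid by seeding against a
sufficiently large interactome. Note also that walktrap legitimately
splits a dense, internally unstructured block into two or three
sub-modules; recovery is therefore assessed on the union of
significant-module genes, the same per-disease union the cross-disease
analyses use.

## Cross-disease comparison and enrichment

`disease_similarity_matrix()` computes pairwise Jaccard indices between
per-disease unions of significant-module genes. `group_shared_modules()`
builds a graph over individual significant modules, linking modules of
*different* traits whose gene-level Jaccard index reaches the threshold
(default 0.7, following the stated methods; a figure caption reads "> 0.7"
and the threshold is configurable), and reports connected components
spanning at least two traits. Single-link closure (connected components)
was chosen over requiring all-pairs overlap because it is the standard
reading of "groups of overlapping modules"; the alternative would only
shrink groups.

`fisher_enrichment()` performs one-sided over-representation tests: the
p-value for a term with $K$ background hits, query size $n$ and $k$ query
hits is the upper hypergeometric tail, identical to the one-sided Fisher
exact test of the 2×2 table. Annotation sets are intersected with the
background first; terms without background hits are skipped; BH adjustment
runs across tested terms. The background defaults to whatever universe the
caller supplies — for module enrichment, the interactome genes present in
the annotation is the sensible choice.

## Benchmarking

`split_gold_standard()` derives two positive sets from a gene–disease
association score map: genes strictly above the third quartile (type-7
linear-interpolation quantile, R's default; the quantile convention is
configurable) and genes attaining the maximum. `roc_auc()` scores how well
propagation ranks positives above the rest of the scored universe, with
the Mann–Whitney pair-counting AUC (ties count one half); the stepwise ROC
curve is returned and its trapezoidal area equals the pair-count AUC
identically, which the tests assert along with agreement with the pROC
package. The negative universe is all scored genes outside the positive
set; the source analysis does not state its negative set, so this is the
package's choice.

The synthetic analogue of the benchmark plants 30 disease genes in one
block, seeds from a random half, and evaluates the AUC of the held-out
half among all non-seed nodes; across 20 replicates the mean AUC is about
0.92, comfortably above the 0.7 reference line, and is reported by
`scripts/acceptance.R` (averaged over replicates — the corresponding
real-data figure averages over diseases and gold-standard sets).

## Multi-omics integration

`significance_a()` implements the Perseus-style outlier statistic for
(averaged) log ratios: with $r_0$ the median and $r_{\pm 1}$ the
84.13th/15.87th percentiles,

$$z = \frac{r - r_0}{r_1 - r_0} \; (r > r_0), \qquad
  z = \frac{r_0 - r}{r_0 - r_{-1}} \; (r < r_0), \qquad
  p = \tfrac{1}{2}\,\mathrm{erfc}\!\left(\frac{z}{\sqrt 2}\right).$$

The asymmetric normalization makes the statistic robust to skewed ratio
distributions; $p = 0.5$ at the median and decreases strictly on each
side. At least 8 ratios are required for the percentiles to mean anything,
and a degenerate spread (a one-sigma percentile equal to the median)
raises an error. The implementation is tested against an independent erfc
oracle and against Monte-Carlo normal calibration ($z \approx 2$,
$p \approx 0.0228$ at the 97.72nd percentile).

`integrate_expansions()` intersects the significant-module gene unions of
the three layers and reports pairwise and triple overlaps (the
inclusion–exclusion identity is asserted on every run in the tests).
`select_concordant_candidates()` keeps triple-overlap genes significant at
$\alpha$ (default 0.05) in *both* omics layers with sign-concordant log2
ratios — the operational reading of "corresponding changes" at transcript
and protein level. No fold-change magnitude cutoff is applied, since none
is stated; the candidate list shrinks monotonically as $\alpha$ decreases.
Reproducing the original studies' specific overlap counts and named
candidates requires their archived datasets and is out of scope.

## Morphometrics

### Form factor

$\mathrm{FF} = 4\pi\,\mathrm{area}/\mathrm{perimeter}^2$: 1 for a circle,
small for polarized, arborized outlines, scale-invariant. `measure_mask()`
computes it from a binary mask with exactly one connected foreground
component (4-connectivity): area is the foreground pixel count times
`pixel_size`², and the perimeter is the marching-squares contour of the
mask at level 0.5 (including hole boundaries), lightly smoothed with a
circular 3-point moving average of the polygon vertices. The smoothing
removes the staircase bias that otherwise inflates curved perimeters by
~6% (a raw pixel-edge perimeter would inflate a circle's by 27%). Measured
behaviour on generated shapes at a 128-px canvas: disks within 2% of
FF = 1, rectangles within ~3% of the analytic value, squares within 5%
once the side exceeds roughly 40 px. For very small compact shapes
(~10 px) the fixed-size corner cuts bias FF upward by up to ~10%; users
measuring small objects should work at higher resolution. Whether a
convex outline or the full stained-mask perimeter is used is a data
question, not a package decision — the function measures the mask it is
given.

### Particle density profiles

`particle_density_profile()` bins particle distances from a process tip
into half-open segments $[i w, (i+1) w)$ — by default fifteen 1-µm bins
across the distal 15 µm — and divides counts by supplied per-bin volumes
(µm³). Particles at or beyond the segment end are excluded; a particle
exactly on an interior bin edge belongs to the upper bin. How per-bin
volumes are estimated from image stacks is upstream of this package;
volumes are inputs. Distances are straight-line distances for synthetic
data; curvilinear distance along skeletonized processes is out of scope.

### Volume ratio and area overlap

`volume_ratio()` is the plain object/region volume quotient (e.g.
mitochondrial density of a process). `area_overlap_percent(a, b)` is
$100\,|a \cap b| / |a|$ — the percentage of the first mask covered by the
second, deliberately asymmetric (share of mitochondrial area overlapping
transporter territory, not vice versa).

### Orientation dispersion

`dispersion_factor()` estimates local structure orientation at each pixel
from the intensity gradient (central differences; orientation is
perpendicular to the gradient, so 0° runs along the first matrix axis),
accumulates a gradient-energy-weighted histogram over $[-90°, 90°)$ in 2°
bins, and fits a four-parameter Gaussian (amplitude, mean, sigma,
baseline) with the histogram recentered on its modal bin so the fit never
straddles the circular wrap. The dispersion factor is the fitted sigma in
degrees. This gradient-based orientation map is statistically equivalent
to Fourier-components directionality analysis for the orientation
histogram, and simpler to specify. Two degenerate regimes bypass the
nonlinear fit, by design: a near-delta histogram (weighted sd below one
bin, e.g. a noiseless grating) returns the weighted circular mean and sd
directly, floored at the one-bin quantization sd, with goodness 1; a
near-flat histogram (white noise) falls back to moment-matched mean and
sigma with amplitude and baseline from a linear fit, yielding a large
dispersion (~52° for uniform orientations) and goodness near 0. A flat
image with zero gradient energy is an error. The estimator is rotation
equivariant: rotating a grating shifts the fitted mean by the rotation
angle (±2°) and leaves sigma unchanged (±2°), which the tests assert. Note
that per-pixel gradient orientations are noise-sensitive, so sigma grows
quickly with additive image noise; comparisons should hold imaging
conditions fixed.

### Track speeds

`track_mean_speed()` is the primary summary: total stepwise path length
over elapsed time (µm/s). The net-displacement alternative
(`track_net_speed()`, first-to-last distance over elapsed time) is always
≤ the stepwise speed and is emitted alongside it by
`track_speed_summary()`, which consumes standard particle-tracker exports
(`track_id`, `frame`, `x`, `y`). The source analysis does not state which
definition its tracking plugin reported; the stepwise mean is the
conventional "mean speed" and is the default.

## Synthetic data: what it emulates and what it does not

`make_planted_interactome()` samples a stochastic block model: blocks play
the role of functional neighbourhoods/disease communities, and seed genes
are drawn from designated blocks with folded-normal $|N(3,1)|$ weights,
mimicking the dynamic range of $-\log_{10}$ GWAS p-values (a typical
genome-wide hit at $p \approx 10^{-3}$ to $10^{-6}$ after gene-level
collapsing) without claiming distributional realism. The SBM was chosen
over degree-corrected variants because its expected edge counts are
analytic (the tests check a seeded draw against binomial moments);
consequently the generator does *not* reproduce the heavy-tailed degree
distribution, hub structure or densification of real interactomes, and
passing tests say nothing about hub-bias robustness on real data.
`p_in = p_out` is allowed and gives the structureless null used for
type-I-error simulations. Generators restore the caller's RNG state and
are byte-identical across reruns with the same `rng_seed`.

`make_omics_tables()` plants $\pm$`effect_log2` changes with controllable
sign concordance between layers over a Gaussian noise floor, with
two-sided z-test p-values against the known noise sd — it emulates
effect/null separation, not the mean–variance structure or missingness of
real RNA-seq/proteomics. `make_shape_mask()`, `make_orientation_texture()`
and `make_particles_and_tracks()` attach analytic truth (area/perimeter,
stripe angle, speed) used directly by the test suite.

## Numerical choices and defaults

| Parameter | Default | Where | Why |
|---|---|---|---|
| score threshold | 0.75 | `build_interactome` | combined-score cutoff, strict `>` |
| damping $d$ | 0.85 | `personalized_pagerank` | conventional PPR default; not dictated by the method |
| PPR tolerance | 1e-12 (L1) | `personalized_pagerank` | oracle agreement to 1e-10 with margin |
| selection fraction | 0.25 | `select_top_fraction` | upper quartile of the ranking |
| walktrap steps | 4 | `iterative_walktrap` | canonical walktrap default |
| max community | 300 | `iterative_walktrap` | re-clustering ceiling |
| min module size | > 10 | `iterative_walktrap` | module definition |
| KS alternative | greater | `ks_module_significance` | enrichment in high scores |
| KS background | selected | `discover_significant_modules` | type-I control (see above) |
| alpha | 0.05 | several | adjusted-p significance level |
| Jaccard grouping | ≥ 0.7 | `group_shared_modules` | stated methods threshold |
| quantile type | 7 | `split_gold_standard`, `significance_a` | R's default linear interpolation |
| histogram bin | 2° | `dispersion_factor` | resolution/noise trade-off |

Tie-breaks are deterministic throughout (lexicographic at the selection
cutoff); degenerate inputs raise informative errors (empty interactome,
no seed overlap, module equal to its background, degenerate ratio spread,
flat images, fragmented masks).

## Problem sizes used in the checks

The packaged simulations are sized for a desk run: the re-clustering
size-law check uses a 2,000-node, 4-block graph; type-I control uses 200
replicates of a 300-node null graph; planted-block recovery uses 100
replicates of a 1,000-node, 10-block graph; the held-out AUC benchmark
averages 20 replicates of a 500-node graph. The full non-acceptance and
acceptance suite completes in well under a minute on one CPU.

## Known limitations

- No identifier mapping: inputs must already share a gene naming scheme.
- Community detection is walktrap-only; the module interface would admit
  other algorithms but none are wired in.
- The SBM generator omits degree heterogeneity (see above).
- Orientation dispersion is computed from per-pixel gradients without
  tensor smoothing; absolute sigma values are comparable only within one
  imaging/noise condition.
- Raster form factors carry a small positive bias for compact shapes near
  the pixel scale.
- GO term relationships (DAG propagation, term ancestry) are not modelled
  in enrichment.
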