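# glianet

Network propagation, disease-module discovery and astrocyte morphometrics
in R.

## What problem it addresses

Genome-wide association studies yield lists of trait-associated genes
with p-values, but pathway-level disturbances — and their cell
type-specific consequences in glia — are not readable from the hit list
alone. glianet implements a proteogenomic-cellular pipeline for
neurodegenerative disease genetics: it expands GWAS hits over a
protein-interaction network into *disease modules*, compares module
catalogs across diseases and omics layers to nominate candidate genes,
and quantifies the cell-level phenotypes (astrocyte process shape, cargo
density, microtubule organization, mitochondrial transport) that such
candidates are expected to perturb. It is written for computational
biologists who want each stage as a tested, composable function rather
than a monolithic script.

## The model at the core

Seed genes carry weights $w_g = -\log_{10} p_g$ from association tables
(pooled traits keep the per-gene maximum). Weights are diffused over an
undirected simple interactome by personalized PageRank, the fixed point of

$$x = (1-d)\,p + d\,W x,$$

with $p$ the normalized seed vector, $W$ the column-stochastic adjacency
matrix and damping $d = 0.85$ by default. The top 25% of nodes by score is
clustered with iterative walktrap: communities larger than 300 nodes are
re-clustered until the ceiling holds, and communities with more than 10
genes become modules. A module is *significant* when its members' scores
are stochastically greater than the remaining background by a one-sided
two-sample Kolmogorov–Smirnov test, Benjamini–Hochberg-adjusted at
$\alpha = 0.05$. Downstream: Jaccard overlap of per-disease module-gene
unions, grouping of modules shared across diseases at Jaccard ≥ 0.7,
one-sided Fisher (hypergeometric) gene-set enrichment, Mann–Whitney ROC
AUC benchmarking against gold-standard gene sets, the Perseus-style
Significance A outlier statistic
$p = \tfrac12\,\mathrm{erfc}(z/\sqrt2)$ on asymmetric robust z-scores,
and triple-overlap candidate selection requiring sign-concordant,
significant changes in both transcript and protein layers.

The morphometrics half computes the form factor
$\mathrm{FF} = 4\pi\,\mathrm{area}/\mathrm{perimeter}^2$ from binary
masks (sub-pixel marching-squares perimeter), particle densities in 1-µm
bins across the distal 15 µm of a process, mitochondria/process volume
ratios, percent area overlap between channel masks, an
orientation-dispersion factor (Gaussian sigma of the gradient-orientation
histogram) and track speeds from particle-tracker exports.

## Worked example

Everything below runs offline: the synthetic generator plants a disease
community in a block-model interactome with known ground truth.

```r
library(glianet)

syn <- make_planted_interactome(n_blocks = 10, block_size = 100,
                                p_in = 0.2, p_out = 0.01,
                                seed_blocks = 1, n_seeds = 30, rng_seed = 3)
syn$seeds
#> seed set for trait 'synthetic': 30 genes, total weight 91.13

catalog <- discover_significant_modules(syn$net, syn$seeds)
catalog$table
#>   module n_genes ks_statistic p_raw p_adjusted significant unsplittable
#> 1      1      33      0.01843 0.969      0.997       FALSE        FALSE
#> 2      2      72      0.00562 0.997      0.997       FALSE        FALSE
#> 3      3      22      0.02033 0.969      0.997       FALSE        FALSE
#> 4      4      18      0.01293 0.984      0.997       FALSE        FALSE
#> 5      5     105      0.96190 0.000      0.000        TRUE        FALSE

planted <- names(syn$blocks)[syn$blocks == 1]
jaccard_index(all_module_genes(catalog), planted)
#> [1] 0.952
```

Module 5 — essentially the planted 100-gene disease block plus a few
bystanders — is the only one whose propagation scores beat the selected
background (KS D = 0.96, adjusted p < 0.001); the other four modules are
background communities that happened to survive selection and are
correctly left non-significant. The union of significant-module genes
recovers the planted block at Jaccard 0.95.

Morphometrics work from masks and tables:

```r
measure_mask(make_shape_mask("disk", size_px = 128))
#> shape: area 8224, perimeter 324.06, form factor 0.9841

prof <- particle_density_profile(c(0.4, 1.2, 1.7, 3.5, 14.2), rep(0.8, 15))
round(prof$densities, 2)
#>  [1] 1.25 2.50 0.00 1.25 0.00 0.00 0.00 0.00 0.00 0.00 0.00 0.00 0.00 0.00 1.25
```

The rasterized disk's form factor lands within 2% of the analytic 1; the
five particles fall into half-open 1-µm bins from the tip and are divided
by the per-bin volumes (0.8 µm³ here), giving particles/µm³.

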