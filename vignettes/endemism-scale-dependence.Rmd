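---
title: "Scale-dependent endemism: methods and design choices"
author: "endemscale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale-dependent endemism: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Endemism — the concentration of range-restricted biodiversity — is routinely
mapped on equal-area grids and used to prioritise conservation. But the maps
depend on three analysis choices that are rarely varied together: the spatial
**grain** (cell edge length), the spatial **extent** over which ranges are
tallied (global, continental, national), and the **taxonomic treatment**
(whether recently diverged populations are treated as one species or
several). `endemscale` implements the full pipeline needed to study this
scale dependence: two endemism metrics, a tree-slicing engine that emulates
taxonomic lumping, percentile hotspot detection, a protected-area gap
analysis, an environmental-heterogeneity mixed model, and a synthetic-data
generator so that everything runs, and is tested, without any external data.

## The metrics

**Weighted endemism.** For a presence–absence matrix on a grid, with $R_t$
the number of cells occupied by taxon $t$ (its global range in cells) and
$r_t$ its range within the local neighbourhood of the focal cell,

$$WE = \sum_{t \in T} \frac{r_t}{R_t}.$$

The neighbourhood defaults to the focal cell alone ($r_t = 1$ for
residents): per-cell endemism maps imply no multi-cell window, and this
choice yields the exact conservation identity $\sum_{\text{cells}} WE = |T|$
that the test suite asserts to $10^{-9}$. A Manhattan-radius neighbourhood
parameter is exposed for users who want the windowed variant. Ranges are
counted in cells, not km²: cells are equal-area, so the two differ only by a
constant factor.

**Phylogenetic endemism.** With $\{I\}$ the set of branches connecting a
cell's residents to the root, $L_i$ the length of branch $i$ expressed as a
proportion of total tree length, and $R_i$ the number of cells occupied by
the union of the branch's descendant ranges,

$$PE = \sum_{i \in I} \frac{L_i}{R_i}.$$

Each branch is counted once per cell regardless of how many resident tips
descend from it. Under the proportional normalisation and complete tip
sampling, $\sum_{\text{cells}} PE = 1$ exactly (each branch contributes
$R_i \cdot L_i / R_i = L_i$), a second identity the tests assert. A raw-Myr
mode (`normalized = FALSE`) is available for users wanting unnormalised
units. Taxa present in the community but missing from the tree are dropped
with a warning rather than grafted in at random: random placement is known
to inflate phylogenetic endemism.

## Tree slicing and taxonomic lumping

Lumping at time depth $d$ merges every maximal clade whose crown node is
*strictly* younger than $d$; a node exactly at the slice age is not
collapsed. The strict inequality is an arbitrary but deterministic tie rule;
with continuous branch lengths ties have probability zero, and with integer
depths the rule means "divergences younger than $d$ Myr merge". Two
boundary conventions complete the definition: depth 0 returns singleton
tips, and any depth at or above the root age returns a single set (the whole
tree collapses). Collapsing replaces each tip set by one tip whose pendant
branch extends to the present, so the lumped tree keeps the original root
height and remains ultrametric; the lumped range is the union of member
ranges. Because a union can only be at least as large as each member range,
per-cell WE is provably non-increasing along any depth series — the
mechanism behind hotspot loss under lumping — and the acceptance suite
checks it with zero tolerance for violations. Splitting, the reverse
manipulation, is deliberately not implemented: there is no defensible way to
invent sub-species ranges from the available inputs.

## Extent restriction and the inflation theorem

Restricting the extent to a continent or country keeps only cells whose
centroids carry that region's label and recomputes occupancy within the
region. For regional PE the package keeps the **full** tree: branch
proportions $L_i$ still refer to the full tree length, and tips whose taxa do
not occur in the region simply contribute zero occupancy
(`absent_tips = "zero"`). This was a genuinely open design point. The
alternative — pruning the tree to regional taxa and renormalising by the
pruned tree length — redistributes branch proportions and can move per-cell
PE in either direction, destroying the very mechanism extent restriction is
meant to expose. With the full-tree convention, every ancestral branch of a
regional cell satisfies $R_i^{\text{regional}} \le R_i^{\text{global}}$
while $L_i$ is unchanged, so regional PE $\ge$ global PE holds cell-wise as
a theorem (strictly when any ancestral range is truncated by the border),
and it is tested with zero violations across 100 random worlds. This is the
formalisation of the border-inflation effect: a taxon barely entering a
country looks maximally endemic there.

## Hotspots and protection

Hotspots at probability $p$ (conventionally 2.5% and 5%) are the cells with
values at or above the $(100-p)$-th percentile of the surface. The quantile
definition is the linear-interpolation type-7 estimator — the source
procedure does not state one, so the common default is fixed and documented.
Two further choices: the percentile is computed over *occupied* cells only
(structural zeros from empty cells would make thresholds grid-shape
dependent; a switch includes them), and ties at the threshold are all
included, which is deterministic and conservative for conservation use (the
hotspot fraction may exceed $p$ under ties). A hotspot cell "meets"
protection when its protected fraction is at least the target, default 10%,
the conventional minimum coverage target; the report is the proportion of
hotspot cells meeting it.

## Environmental heterogeneity and the mixed model

Heterogeneity is the within-cell sample standard deviation (denominator
$n-1$; conventional, the source is silent) of each of four fine-resolution
layers: temperature, precipitation, productivity, elevation. Under grain
aggregation the subcells of the merged block are pooled before taking the
SD, so coarser grains integrate more landscape — on gradient-bearing
synthetic layers the median per-cell SD is non-decreasing with grain, which
is asserted as a median trend rather than cell-wise (smoothing noise can
locally reverse it).

The model is $Y_i = x_i\beta + s_i + \varepsilon_i$: endemism per occupied
cell regressed on the four heterogeneity terms plus a spatial
autocovariate, with a random intercept per continent, fit by maximum
likelihood (not REML, so nested fits are likelihood-comparable; per-term
likelihood-ratio tests are exposed as an option, Wald 95% intervals are the
primary report). All predictors are standardised to mean 0, SD 1, making
coefficients comparable effect sizes; the tests assert the fit is invariant
to shifting/scaling raw predictors. The autocovariate of a cell is the
weighted mean of the response over lattice neighbours within order 1 (4 rook
neighbours) or order 2 (adds the ring at Manhattan distance 2), with
inverse-distance or equal weights, computed once from the response itself
and not iterated. The fitting engine is `lme4::lmer`; the package's
contract is the model construction (standardisation, predictor set,
grouping), which is what the calibration tests exercise: with data simulated
under the model at known $\beta = (0.5, 0, 0, 0, 0.3)$, mean estimates land
within 0.1 of truth and interval coverage stays in [88%, 99%] over 200
replicates.

## The synthetic world

The generator is first-class, tested code, and its defaults are a stated
world, chosen once on domain realism:

* **Trees.** Independent pure-birth (Yule) draws sharing a tip-label set
  stand in for a posterior sample — downstream code only needs topology and
  branch-length variation. The sampling variant is explicit: with $k$
  lineages the next split waits $\mathrm{Exp}(k\lambda)$, and the tree is
  taken just before the $(n{+}1)$-th birth, giving
  $E[\text{root height}] = \sum_{k=2}^{n} 1/(k\lambda)$ — the closed form
  the simulator is tested against. The default $\lambda = 0.05$ per Myr is
  a realistic vertebrate speciation rate: a 100-tip tree has expected root
  height near 84 Myr, so Myr-scale lumping depths are shallow cuts, as they
  are for real bird and amphibian phylogenies.
* **Ranges.** Sizes follow a lognormal truncated to $[1, n_{\text{cells}}]$
  (the standard right-skewed range-size model; the real distributions are
  not published, so the law is a documented tunable), grown as contiguous
  spreading-dye patches on rook adjacency — rook matches square equal-area
  cells and keeps the growth model simple.
* **Environment.** Each cell holds a $k \times k$ block of subcells
  ($k \ge 2$, default 4). Layers are smoothed Gaussian noise (spatially
  autocorrelated by construction) plus a latitudinal gradient; elevation
  carries no gradient. An infinite correlation length degenerates to a
  constant layer, the zero-heterogeneity limit used in tests.
* **Regions.** Continents, then countries within continents, grown by
  round-robin spreading dye from random seeds: contiguous and nested by
  construction.
* **Protection.** Independent Beta draws with mean 0.15 (close to the
  global terrestrial protected fraction) and a small shape parameter, giving
  the right-skewed, most-cells-near-zero pattern of real coverage. Spatial
  clumping of protected areas is *not* modelled; the analysis only consumes
  per-cell fractions.

What a green test establishes, and what it does not: the synthetic world
exercises every mathematical property of the pipeline (identities, oracle
equivalence, monotonicities, calibration) but does not emulate coastlines,
climate physics, niche-driven range placement, or spatially clumped
protection. Conclusions about *real* endemism patterns require real data;
the package's claim is that the machinery is correct and the stated
mechanisms (lumping monotonicity, extent inflation) are exact.

## Numerical conventions

* Cell indexing is 0-based row-major from the south-west corner; coordinates
  are abstract planar km in an equal-area frame (no projection code — the
  equal-area property is all that matters and synthetic grids have it by
  construction).
* Polygon ranges rasterize by cell-centroid-in-polygon (documented dialect;
  area-overlap is not implemented).
* Grids not divisible by an aggregation factor drop trailing rows/columns
  with a warning, keeping coarse cells equal-area; taxa stranded in the
  dropped margin are dropped with a second warning.
* Ultrametricity is validated on read within $10^{-6}$ Myr; node ages are
  measured from the mean tip depth so near-ultrametric trees get consistent
  ages. Collapse preserves root height to the same tolerance.
* Region labels aggregate by the centroid rule; for even factors the
  centroid falls on a fine-cell corner and the tie is broken to the
  north-east, deterministically. Protection aggregates by the block mean
  (equal-area cells make this the exact area-weighted fraction).
* Posterior integration is the per-cell median across trees; even counts
  take the midpoint of the two central values.
* Every generator is a pure function of its arguments including the seed;
  identical seeds give identical worlds, and the experiment runner adds no
  randomness of its own, so re-runs are byte-identical.

## Known limitations

* WE under lumping is the primary lumping analysis; PE under lumping is
  supported through the same collapse machinery but is secondary.
* The mixed model reports Wald intervals; with few continents the
  random-intercept variance is weakly identified (singular fits are possible
  and reported by `lme4`), though fixed-effect calibration is unaffected in
  the tested regimes.
* Real-data ingestion (range polygons from shapefiles, protected-area
  databases, climate rasters) is out of scope; inputs arrive as cell lists,
  plain polygons, Newick and delimited tables.
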