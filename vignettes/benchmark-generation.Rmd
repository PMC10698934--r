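---
title: "Generating synthetic biclustering benchmarks with bicsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating synthetic biclustering benchmarks with bicsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Why plant biclusters?

Biclustering algorithms look for submatrices — a subset of rows $I$ and a
subset of columns $J$ of a data matrix $A \in \mathbb{R}^{n \times m}$ —
whose values obey a homogeneity (coherency) law. Real datasets carry no
ground truth: one can measure how internally coherent a reported bicluster
is, but never how many planted patterns an algorithm missed or invented.
`bicsim` addresses this by *planting* biclusters with known membership and
known coherency into a synthetic matrix, then emitting the solution
alongside the data so external metrics (recovery, relevance, Jaccard-type
scores) become computable.

A generation run is one seeded pass through six stages: background
sampling, bicluster sizing, overlap planning, frame placement, pattern
planting, plaid composition, and quality degradation. Every random draw
comes from the single stream seeded by `seed`, so a `(spec, seed)` pair is
bit-reproducible — the settings JSON written next to each dataset is
sufficient to regenerate it byte for byte.

## The coherency model

Within a bicluster $B = (I, J)$ the value $b_{ij}$ is tied to a seed value
$\mu$, a row factor $\alpha_i$ and a column factor $\beta_j$. The coherency
named on a dimension describes how values change *along* that dimension:

| rows            | columns         | law                                      | alphabets |
|-----------------|-----------------|------------------------------------------|-----------|
| constant        | constant        | $b_{ij}=\mu$                             | any       |
| none            | constant        | $b_{ij}=\alpha_i$                        | any       |
| constant        | none            | $b_{ij}=\beta_j$                         | any       |
| additive        | additive        | $b_{ij}=\mu+\alpha_i+\beta_j$            | numeric   |
| constant        | additive        | $b_{ij}=\mu+\beta_j$                     | numeric   |
| additive        | constant        | $b_{ij}=\mu+\alpha_i$                    | numeric   |
| multiplicative  | multiplicative  | $b_{ij}=\mu\,\alpha_i\,\beta_j$          | numeric   |
| constant        | multiplicative  | $b_{ij}=\mu\,\beta_j$                    | numeric   |
| multiplicative  | constant        | $b_{ij}=\mu\,\alpha_i$                   | numeric   |
| order-preserving| none            | one shared row order sorts every column  | any       |
| none            | order-preserving| one shared column order sorts every row  | any       |

These eleven pairs are the legal combinations; anything else (e.g. additive
rows with multiplicative columns, or additive patterns on symbols) is
rejected at validation with a message naming the offending field.

**Factor distributions.** The coherency laws fix the algebra but not the
law of $\mu$, $\alpha$, $\beta$; these are design choices of this package.
$\mu$ is uniform over the alphabet. Additive factors are uniform on the
interval that keeps $\mu+\alpha+\beta$ inside $[\min,\max]$ (each of two
additive dimensions receives half of the available slack). Multiplicative
factors are uniform on $[1, s]$ with $s = (\mathrm{cap}/|\mu|)^{1/2}$ for
two multiplicative dimensions (cap $= \max$ for $\mu > 0$, $|\min|$
otherwise), so products never leave the alphabet and row scalings stay
positive; seed values within $0.1\%$ of zero are redrawn. Integer alphabets
sample integer factors directly, so planted grids are exactly integral and
the stored factors reproduce the grid bit-exactly — a property the test
suite asserts.

**Order-preserving patterns.** Each row receives values sampled *without
replacement* (distinct symbols, distinct integers, or almost-surely
distinct reals), sorted, and laid out under one shared column permutation;
ties would make "a permutation that linearly orders every row" ambiguous,
which is why distinctness is enforced. One deliberate degradation: an
integer alphabet narrower than the bicluster width (say counts in
$[0,100]$ under a 600-column pattern) cannot supply distinct values, and
those rows fall back to with-replacement draws, giving non-decreasing
rather than strictly increasing rows. Symbolic order is rank order in the
user's symbol list, and symbolic order-preserving biclusters wider than
the symbol list are rejected.

**Time profiles.** When biclusters are contiguous (the column set is a run
of consecutive indices, modelling consecutive time points) and the columns
carry the order-preserving coherency, the shared permutation can be pinned:
`monotonically-increasing` (identity), `monotonically-decreasing`
(reversal), or `random`. Row sets are never forced to be contiguous —
contiguity is a time-axis concept.

## Plaid composition

Cells covered by several biclusters combine their contributions
$\theta_{ijt}$ (membership indicated by $\rho_{it}\kappa_{jt}$) under the
configured plaid coherency: `additive` sums the covering layers,
`multiplicative` multiplies them, `interpoled` averages them, and `none`
keeps the last-generated bicluster's value. Two choices deserve note:

* the *average* in the interpolated mode divides by the number of
  biclusters **covering the cell**, not by the total bicluster count; a
  global divisor would systematically shrink values wherever few
  biclusters overlap, which contradicts the intent of averaging layers;
* the background contributes **no layer** to covered cells — covered
  cells are fully determined by their biclusters.

Composed values are clipped to the alphabet (integers rounded first);
clipped cells are flagged in the solution record so evaluators can exclude
them. Uncovered cells keep their background value bit-exactly.

## Structure: sizes, overlap, placement

Row and column counts per bicluster are drawn from fixed, integer-uniform
or rounded-Gaussian distributions, clamped to $[1, \text{dimension}]$. A
configured fraction of biclusters is assigned to overlap groups of between
2 and `max_interactions` members (so no cell is ever shared by more than
`max_interactions` biclusters); the remainder are singletons, placed
cell-disjoint from everything else. Within a group, consecutive biclusters
share `round(pct_rows/100 * |I|)` rows and `round(pct_cols/100 * |J|)`
columns — percentages taken of the *smaller* partner, since the reference
frame is otherwise ambiguous — and the shared-cell count is capped by
`pct_elements` (shared columns, then rows, are reduced until the cap
holds; a cap of 0 yields row-only or column-only sharing).

Because every frame is a Cartesian product $I \times J$, two frames share
a cell exactly when their row sets *and* column sets both intersect, which
makes disjointness checks cheap. Placement is rejection sampling with a
budget of 1000 draws per frame; on exhaustion a deterministic sweep scans
column runs left to right and takes the first position with enough
unblocked rows. Configurations that are geometrically over-packed fail
with an error naming the offending bicluster and matrix sizes — unless
`relax_placement = TRUE`, which places the remaining frames with unplanned
overlap instead (the composition and the solution record stay correct;
only the disjointness guarantee is waived). The gene-expression preset
enables this flag because its published bicluster load exceeds the matrix
area.

## Backgrounds and mixed-type data

Four backgrounds generate the cells outside all biclusters: `uniform` over
the alphabet, `normal` (numeric only), `discrete` with user symbol
probabilities, and `missing` (a null background). Normal draws falling
outside $[\min,\max]$ are **clipped, not resampled** — resampling would
truncate silently and change the effective variance; clipping keeps the
configured moments in the interior and is visible (mass at the bounds).

Heterogeneous datasets hold exactly `round(pct_numeric/100 * m)` numeric
columns at randomized positions, one numeric and one symbolic alphabet
applied per column type. Each planted bicluster spans columns of a single
attribute type: value algebra across mixed-type cells is undefined, so
patterns requiring numeric data are forced onto numeric columns and the
rest choose their type with probability `pct_numeric/100`. Contiguity is
not supported on heterogeneous data (a column run would straddle types).

## Quality: missing, noise, error

Degradation is configured per region — the background and the biclusters
independently. In each region `round(pct/100 * size)` cells per role are
drawn without replacement, with mutually exclusive roles. The noise
threshold $\delta$ separates the two perturbation classes on numeric data:
noisy cells move by $u$ with $0 < |u| \le \delta$, erroneous cells by
$|e| > \delta$, both drawn uniformly and directed so the deviation
survives clipping to the alphabet (validation therefore requires
$\delta < \text{span}/2$ when errors are requested, $\delta \ge 1$ on
integer alphabets when noise is requested, and rejects noise at
$\delta = 0$ outright, since no non-zero $|u| \le 0$ exists). Symbolic
noise replaces a symbol by an adjacent-rank one; symbolic errors draw
uniformly from ranks at distance $\ge 2$. A cell inside two overlapping
biclusters is eligible once, charged to the lower-indexed bicluster.
Quotas are exact cell counts, not expectations, and the injected mask
(missing / noisy / error indices plus $\delta$) is exported in the
solution JSON for noise-aware scoring.

## The virtual error metric

To score the internal homogeneity of any numeric submatrix the package
implements row standardization with the *population* standard deviation
(the per-row denominator convention is otherwise arbitrary; the population
form keeps the estimator scale-free at any width),

$$\hat b_{ij} = \frac{b_{ij} - \mu_i}{\sigma_i},$$

the virtual pattern $\hat\rho_j = \frac{1}{|I|}\sum_i \hat b_{ij}$, and
the virtual error

$$\mathrm{VE}(B) = \frac{1}{|I||J|}\sum_{i}\sum_{j}
  \left|\hat b_{ij} - \hat\rho_j\right|.$$

Rows with $\sigma_i = 0$ standardize to zeros rather than `NaN`; this is
what makes VE exactly 0 on constant biclusters, and together with the
positive multiplicative row factors it makes VE vanish (to machine
precision) on every noise-free constant, additive and multiplicative
planted pattern, while i.i.d. submatrices score well away from zero.
Order-preserving biclusters need not reach zero but score consistently
below shuffled controls of the same values. VE is invariant to per-row
affine maps $b_{ij} \mapsto a_i b_{ij} + c_i$ with $a_i > 0$. An
element-level Jaccard score over unions of bicluster cell sets is included
as solution-comparison plumbing (two empty solutions score 0 by
convention).

## Presets

`preset_spec()` reproduces three families of configurations: three
illustrative datasets (single constant bicluster; two fully-overlapping
constant biclusters under the additive plaid with 50% shared rows,
columns and elements; ten contiguous monotonically-decreasing
order-preserving biclusters), six 1000×100 single-bicluster baselines
spanning real, symbolic, binary, integer, contiguous and heterogeneous
data, five domain-mimicking settings (microarray expression, ratings,
term–document, clinical records, fMRI windows), and an expression-like
660×180 matrix with 52 planted four-column constant-row biclusters,
N(0,45) background, Gaussian row counts N(73,3), 40% bicluster noise under
threshold 9 and 10% bicluster errors.

Two interpretation notes, flagged here because the sources of these
configurations leave gaps. First, the domain-mimicking settings specify
quality ("99.8% missing", "10% noise") but not the underlying background
law; this package fixes one per domain — N(0,30) for expression on
$[-100,100]$, uniform integers in $[1,5]$ for ratings, uniform counts in
$[0,100]$ for term–document data, a uniform 50/50 real–symbolic mix for
clinical records, uniform reals for the fMRI-like setting — chosen to
match each domain's usual value semantics. Second, the quality block of
the expression-mimicking configuration is typeset ambiguously in its
source; the preset fixes the reading noise = 40% of bicluster cells at
threshold 9, errors = 10% of bicluster cells, background clean. Both are
package interpretations, not reported facts. The two largest
domain-mimicking presets (ratings at 200000×30000 and term–document at
30000×20000) describe matrices beyond interactive scale; they validate
and serialize, and scaled-down replicas (same background and quality, a
tenth of each dimension, a proportionally reduced bicluster load) are what
the test suite and the acceptance script generate.

## Numerical and testing choices

* The missing marker is `NA`, rendered as an empty field in the TSV.
* Numeric cells are serialized at 15 significant digits, which round-trips
  doubles through the text formats in practice.
* Identifiers in all output files are 0-based (`row_0`, `col_0`), matching
  the headers of the dataset table; in-memory R objects are 1-based.
* The test suite exercises the generator at deliberately small problem
  sizes — property sweeps over 100 random specs at up to 40×40, the
  composition oracle at 20×20, the scaled term–document replica at
  3000×2000 — so the full suite and the acceptance script each run in
  well under a minute on one core.
* Passing tests demonstrate the *contractual* properties (coherency
  algebra, quotas, determinism, closure) on synthetic draws; they do not
  certify that any preset statistically resembles a particular real
  dataset, which depends on the chosen backgrounds and factor laws above.

## Known limitations

* No structured (row/column-correlated) or heteroskedastic noise; the
  perturbation law is uniform because the threshold contract specifies
  magnitudes, not shapes.
* Plaid arithmetic on symbolic overlap regions is undefined and rejected;
  symbolic overlaps require the last-writer-wins mode.
* `relax_placement` waives the cell-disjointness guarantee for singletons;
  over-packed configurations either fail loudly or overlap informally —
  there is no optimal packing.
* Per-bicluster pattern lists are assigned round-robin, not optimally
  matched to bicluster shapes.
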