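---
title: "Methods: models, parameters and design choices in fsmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in fsmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models and
their assumptions, the parameters that matter, what the simulator does and
does not emulate, the numerical choices, and the places where the design
was genuinely open and we had to decide.

## 1. The genetic model

A single outbred full-sib (CP) family: two heterozygous parents, unknown
linkage phases, offspring genotyped at codominant markers. Each marker
carries one of five segregation patterns. Writing the first-listed parent
as maternal:

| code    | maternal | paternal | classes        | ratio    | informative |
|---------|----------|----------|----------------|----------|-------------|
| `abxcd` | a/b      | c/d      | ac ad bc bd    | 1:1:1:1  | both        |
| `efxeg` | e/f      | e/g      | ee ef eg fg    | 1:1:1:1  | both        |
| `hkxhk` | h/k      | h/k      | hh hk kk       | 1:2:1    | both, but `hk` is origin-ambiguous |
| `nnxnp` | n/n      | n/p      | nn np          | 1:1      | paternal    |
| `lmxll` | l/m      | l/l      | ll lm          | 1:1      | maternal    |

The paper never fixes which cross-code side is which parent; the
convention only affects labels, never estimates.

Everything downstream works on **chromatid origins**: for each offspring,
marker and parental meiosis, which of the parent's two chromatids (A/B)
was transmitted. Phase 0 ("coupling") puts the first allele on chromatid
A. A genotype class maps deterministically to origins given phases, with
three sources of `UNKNOWN`: missing calls, uninformative parents, and the
`hk` class of `hkxhk` markers (both allele-to-parent assignments are
consistent). We never guess ambiguous origins deterministically; the
multipoint sampler integrates over them.

Meioses are modelled without crossover interference, so the Haldane map
function is exact for the simulator and is the default for reporting
(`r_to_cM()`; Kosambi available as an option).

## 2. Pipeline stages and their tunables

### Grouping

Pairwise Pearson X² of the joint genotype-class table, converted to a
LOD-type score as `X²/(2 ln 10)` (the standard χ²→LOD bridge; the
original transformation formula is not restated anywhere we could verify,
so we use the standard one). Cells with zero expected count are dropped.
Single-linkage components are scanned over a LOD threshold grid
(default 2–20 by 0.5); at each threshold, components smaller than
`min_group_size` (default 1% of markers, floor 3) are merged into the
large component they split from one grid step earlier, or discarded when
they were already separate at the grid minimum. The smallest threshold
whose simplified component count hits the target chromosome number wins.

### Two-point analysis and phasing

One generic engine serves all 15 segregation-type pair combinations: the
four chromatid transmissions of the two meioses are enumerated with
probabilities {1−r, r}·{1−r, r} and mapped to observable class pairs;
the multinomial likelihood of the joint class counts is maximised over r
(one-dimensional optimisation, r clamped to [1e-4, 0.5]) for each
admissible relative phase pair; LOD is the base-10 ratio against r = 0.5.

For speed, the full matrices used by ordering take a count shortcut: under
anchored phases the per-parent discordance fraction of determinable
origins is the MLE for fully informative pairs. One pathology demands the
full likelihood: `hkxhk`×`hkxhk` pairs whose relative phase differs
between the parents. There, a homozygote at one marker implies the
ambiguous `hk` class at the other, so linked pairs have almost no jointly
determinable origins and the few remaining cells are enriched for
recombinants — the count estimate clamps to 0.5 exactly at true
adjacencies. We detect the determinability deficit (per-parent
determinable count below 60% of the expected 25% of jointly observed
offspring) and re-estimate those pairs by likelihood.

Phases are anchored per parent on a maximum-LOD spanning tree (edges
require ≥ `min_informative` = 20 jointly determinable meioses and
LOD ≥ 1), propagating each pair's best relative phase from an arbitrary
coupling anchor. Disagreeing non-tree edges are counted and reported;
phases are identifiable only up to a global flip per parent, and all
evaluation is flip-invariant.

### Ordering

The objective is SARF: the sum of adjacent recombination fractions along
the maternal sub-order plus the paternal sub-order. It is
reversal-invariant and minimised by the true order when the r matrix is a
monotone function of distance.

The search has three safeguards that experience with noisy data forced on
us (each is a package design choice, configurable):

* **Spectral seriation as initialisation and anchor.** The Fiedler vector
  of the graph Laplacian of a similarity kernel `exp(-d/σ)` on the
  pairwise Haldane distances (σ = median pairwise distance) orders the
  markers using every pairwise entry at once. Unlike nearest-neighbour
  chains or geodesic MDS, it is robust both to per-pair noise and to
  isolated outlier entries.
* **Anchored annealing.** Proposals mix the single-locus relocation move
  with segment reversals (relocation alone cannot repair a misplaced
  block). When genotyping errors are pervasive, every pairwise r is
  inflated towards a constant and the *global* SARF minimum becomes an
  estimation-noise artefact — a shortest-tour through spuriously small
  entries that is uncorrelated with the genome. Full-set moves are
  therefore confined to ± `anchor_window` (default 10) slots of the
  seriation rank; the widely spaced skeleton from spatial sampling has
  r contrast above the noise by construction and is annealed without
  restriction.
* **A size-scaled stopping rule.** The acceptance-control parameter
  starts at `c0 = 0.1` (ΔSARF is on the recombination-fraction scale) and
  cools by 0.9 per level of `100·n` proposals. The search stops after
  `max(500, 25·n)` consecutive rejections: with place-anywhere proposals
  the chance that a random move helps shrinks roughly like 1/n², so a
  flat 500 would stop a 200-marker group almost immediately.

Blocked Gibbs multipoint estimation alternates (a) exact joint sampling
of each offspring's complete inheritance vector per meiosis by forward
filtering / backward sampling over the hidden origin chain — missing and
ambiguous cells are integrated over, observed origins are hard evidence —
and (b) a conjugate `Beta(a + k, a + m − k)` draw of each interval r from
its sampled crossover count k among m meioses. The prior weight defaults
to `a = 0.1` rather than Jeffreys' 0.5: on dense maps the prior
pseudo-count adds ≈ a/m per interval to every near-zero interval, which
at hundreds of intervals inflates the map by tens of percent. The
*reported* interval estimate is the posterior mean crossover rate
(mean sampled k divided by m), which carries no pseudo-count at all; the
draws retain the prior so the chain cannot freeze at r = 0. A split-chain
diagnostic (half-means compared on the posterior-sd scale) flags
non-convergence in the result rather than failing silently.

The paper-described feedback in which multipoint estimates refresh the
pairwise matrix between annealing cycles is implemented
(`gibbs_refresh`) but off by default: when the intermediate order is
wrong, the refreshed entries encode the wrong adjacency and measurably
degrade the next annealing pass.

Parental maps are integrated by pooling, per adjacent interval of the
full order, the parental multipoint distances available for that pair
(mean of the defined ones); test-cross stretches fall back to the single
informative parent. Orientation is arbitrary; maps are reported with the
lower-index terminal marker first, and all order metrics take |Spearman|.

### Correction

Singletons are scanned per offspring and meiosis over the determinable
origins in map order; terminal loci never qualify. Cells to resolve are
singletons and missing calls, excluding **suspicious markers**: markers
whose singleton fraction exceeds `max(0.1, 3 × median marker fraction)`.
The adaptive part matters: with 20% cell-level errors *every* marker
carries ≈ 12% background singleton load, and a flat 10% threshold would
flag three quarters of all markers — switching correction off exactly
when it is needed. A marker is suspicious when it stands out from the
background, which reduces to the flat threshold on clean data.

The vote takes the k = 5 nearest determinable, non-singleton loci of the
same offspring chain by cM distance. Singleton correction requires 80%
agreement; the voted origins of both meioses are projected back to a
genotype class honouring segregation type and phases. A singleton whose
vote yields no replacement class is *eliminated* (set missing): the cell
disagrees with both flanks, and keeping it would freeze the iteration at
high error rates. Imputation of missing calls is stricter — unanimity,
with voters drawn from both sides of the cell — because it writes a call
where nothing was observed, and one-sided votes extrapolate across
crossovers.

The pipeline runs up to `n_outer_rounds = 4` rounds of ordering ↔
correction, stopping early once fewer than 0.1% of cells change, then
re-estimates distances by Gibbs on the cleaned matrix with the final
order fixed.

## 3. The simulator and what a green test establishes

`simulate_family()` places markers uniformly at random along each
chromosome, draws segregation types from a configurable mix (default
10/15/25/25/25% for `abxcd`/`efxeg`/`hkxhk`/`nnxnp`/`lmxll`, a
test-cross-heavy mix typical of outbred species), assigns random phases,
simulates both parental meioses as interference-free origin chains
(switch probability = inverse Haldane of the interval), and injects
errors (uniform over the other valid classes — the least-informative
corruption) and missingness i.i.d. across cells. A cell blanked by
missingness loses any injected error. Everything is reproducible from one
seed.

`blockwise_dataset()` reproduces the incremental benchmark: marker blocks
of 100 appended one at a time, each block carrying its own error/missing
rate derived from the printed cumulative aggregates
(`B_b = b·A_b − (b−1)·A_{b−1}`); the printed aggregates are treated as
inputs because a literal per-block "+5%" reading contradicts them.
`simulate_depth_calling()` emulates naive genotype calling at low read
depth (each read samples one allele copy; configurable rule for partially
resolved calls); the published depth table's calling rule is unstated, so
those values are a qualitative reference, not ground truth.

What the simulator does **not** emulate: linkage disequilibrium between
families, segregation distortion, locus-specific or correlated error
processes, read-level artefacts, genotyping uncertainty scores. A green
benchmark therefore establishes that the pipeline recovers order and
repairs uniform random corruption at realistic rates — not that it is
robust to structured artefacts of a particular sequencing platform.

Default benchmark geometry is a single 100 cM chromosome (family size
200). At 200+ markers this is deliberately past the resolution limit of
200 meioses: many adjacent intervals see no recombinant at all, so local
order is partly unidentifiable and estimated map length exceeds the
simulated 100 cM even with perfect correction. Singleton and accuracy
metrics are insensitive to this; exact-order and map-length claims are
only meaningful on identifiable designs (wider spacing or more
offspring), which is how the corresponding tests are constructed. One
further hard limit: adjacent test-cross markers informative in *opposite*
parents share no meiosis, so no method can order them relative to each
other.

## 4. Numerical conventions

* r clamps: [1e-4, 0.5] two-point, [1e-4, 0.499] multipoint.
* Zero-expectation contingency cells dropped from X²; degenerate
  single-row/column tables score LOD 0.
* Pair likelihood tables are cached per (type pair, phase pair) as
  transmission lookup tables; the probability of each cell is a
  quadratic in r.
* Output positions are written with 4 decimals; ties in ordering are
  broken by marker id so reruns are byte-identical.
* All randomness flows through R's RNG from one seed; compiled kernels
  use the R RNG stream, so results are reproducible across the R/C++
  boundary.

## 5. Known limitations

* Single family, diploid, five CP patterns; no selfing/backcross designs.
* Correction can entrench a wrong order if the initial seriation were
  globally wrong; the spectral initialisation and anchoring exist
  precisely to prevent this, but pathological r matrices (e.g. heavy
  segregation distortion, which the simulator does not model) are
  untested territory.
* Imputation accuracy is bounded by `hkxhk` class reconstruction, which
  needs both meiosis origins to be voted correctly.
* Map length on saturated designs reflects the resolution limit and the
  residual error rate, not the simulated truth; compare lengths only
  between runs of the same design.
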