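---
title: "Methods: quantifying nuclear-periphery enrichment in genomic and imaging data"
author: "nucperi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying nuclear-periphery enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucperi)
```

`nucperi` implements the quantitative core of a common experimental design
in heterochromatin biology: a chromatin factor (here motivated by the
PP1-targeting subunit Repo-Man/CDCA2 and its anchor Nup153 at the nuclear
pore basket) is characterized both **genomically** — where do its binding
sites fall relative to subtelomeres, gene features, lamina-associated
domains and histone marks? — and **microscopically** — is the protein, or a
tagged locus, enriched at the nuclear periphery, and does a perturbation
move it? Both halves are served by synthetic-data generators with exact
ground truth, so every statistic in the package can be validated end to end
without external downloads.

## Genomic intervals

### Coordinate model

All interval sets are `GRanges` objects carrying a `Seqinfo` genome; files
use the BED convention (0-based half-open, tab-separated), and conversion
happens only at I/O boundaries. Abutting intervals merge: under the
half-open convention `[0,100)` and `[100,200)` are contiguous bases.
Interval algebra (merge, intersection, overlap counting) is delegated to
`IRanges`/`GenomicRanges`; the test suite nevertheless checks every
operator against an independent per-base boolean oracle on thousands of
random instances, because two of the operators are study-specific
compositions:

* `subtract_control()` removes whole peaks whose **total** base overlap
  with a control pulldown (e.g. GST alone) reaches a threshold. Total
  overlap — rather than overlap with any single control interval — is the
  semantics consistent with a per-base view of the control set.
* `consensus_union()` builds the replicate consensus: every pair of
  replicate peaks overlapping by at least `min_overlap_bp` emits the union
  span of the pair, and the spans are merged. Which coordinates a
  consensus site should keep is a reporting convention rather than a
  mathematical necessity, so all four modes are provided
  (`union`/`intersection`/`rep1`/`rep2`), with union spans as the default:
  it is symmetric in the replicates and keeps each site's full evidence
  footprint.

### Subtelomeric enrichment

Subtelomeres are operationalized as fixed-width terminal windows (default
500 kb per chromosome end, the convention for human chromosomes); windows
are clipped and merged on chromosomes shorter than twice the width.
Enrichment compares the fraction of peaks inside the windows with the
fraction of the genome the windows cover:

* **Membership.** A peak is "inside" if its midpoint is (default), or if
  it overlaps by at least one base. Midpoint membership gives every peak
  exactly one unambiguous assignment and makes the planted-fold generator
  exactly recoverable; any-overlap is provided because reported fold
  values in the literature rarely state their membership convention.
* **Expectation.** The by-chance denominator is the base-pair coverage
  fraction of the windows — the probability that a uniformly placed
  midpoint lands inside.
* **Permutation null.** Each permutation redraws every peak uniformly with
  its length preserved, by default on its own chromosome (preserving
  chromosomal composition), optionally genome-wide with chromosomes
  weighted by length. The p-value uses the add-one rule
  `(1 + #{null >= obs}) / (1 + n_perm)`, so it is never 0 and is
  super-uniform at worst by `1/(1 + n_perm)`. A binomial upper tail at the
  coverage expectation is reported alongside as a closed-form check.
  Every stochastic function takes a mandatory explicit seed and restores
  the caller's RNG state.

### Exact tests and co-occurrence

`fisher_exact()` computes the hypergeometric exact test directly from
`dhyper`, with the standard point-probability rule for the two-sided case
(all tables no more probable than the observed one, relative tie tolerance
1e-7). It is written for bulk use — the suite enumerates every 2x2 table
with margins up to 20 against an independent `lchoose`-based oracle — and
agrees with `stats::fisher.test` to numerical precision; the test suite
checks both routes.

Reported Fisher p-values for feature annotation and histone-mark
co-occurrence rarely define the underlying contingency construction.
The package's declared convention: observed peaks versus a pooled
background of `n_shuffle` length-matched, same-chromosome shuffles of the
peak set, tabulated as `[obs_in, obs_out; shuf_in, shuf_out]`. This
controls for peak length and chromosomal composition. Raw p-values are the
comparison surface (matching how such figures are printed);
Benjamini-Hochberg adjusted values are reported alongside.

One subtlety is documented as a limitation: with variable peak lengths,
longer peaks overlap both marks more often, which inflates the joint
overlap of the shuffled background relative to any length-independent
planted signal. This length confounding is intrinsic to the
observed-versus-shuffled design (and equally affects real peaks, where it
is a feature: it is controlled for). The co-occurrence calibration
benchmarks therefore use the generator's constant-length mode, where the
confounder vanishes.

## Microscopy

### Segmentation and erosion shells

Nucleus masks are produced by a declared default recipe — global Otsu
threshold, hole filling, 8-connected components, minimum-area filter,
labels sorted by descending area — or supplied externally and used
verbatim: masking recipes are rarely reported in enough detail to
reproduce, so the default here is declared rather than inherited.

Radial positioning uses the erosion-shell construction: the Euclidean
distance transform from background is computed over the mask and in-mask
pixels are binned into `K = 5` shells of **equal area** by area-quantiles
of the distance values (shell 1 outermost). Equal-area construction is
chosen over repeated fixed-width erosion because it is
resolution-independent and gives the natural null — uniformly placed
points land in each shell with probability `1/K` — which is how shell
histograms are read; fixed-width binning is available as an option. Ties
in the distance values are broken outward (a tied class goes to the lower
shell), so shell areas deviate from `total/K` by at most one tie class —
under 2% of the mask for ellipses of 10^4 pixels. The partition commutes
exactly with 90-degree rotations.

Shell distributions of two conditions are compared per shell by Fisher's
exact test on shell-membership counts and overall by a chi-square test on
the shells-by-conditions table (zero-margin shells dropped as
uninformative).

### The peripheral-enrichment ratio

The rim statistic is defined on a line profile across the nucleus: the
two edge maxima (Max1, Max2) are averaged and divided by the median of
the central plateau. The edge and plateau windows are free choices, so
they are parameters: each edge window is the first/last
25% of in-mask samples and the plateau is the central 50%, by default.
The profile runs along the mask's major axis through the centroid (in
interactive practice such profiles are hand-drawn chords across the
nucleus), sampled at unit-pixel steps by
bilinear interpolation, and each sample averages a short perpendicular
band (`band_px = 7`, the "line width" of interactive profile tools)
restricted to in-mask positions.

Two numerical properties matter for interpretation. The ratio is invariant
under multiplicative intensity rescaling but **not** under additive
offsets — background must be subtracted first (a `background` argument is
applied inside `line_profile()`, with clamping at zero). And because the
numerator is a maximum, pixel noise biases the ratio upward: with the
band average, rim-free nuclei read 1.00 within 0.05 at signal-to-noise 20
and within 0.10 at signal-to-noise 10 (planted rim ratios are still
recovered within 10% at signal-to-noise 10, because the bias is small
relative to a real rim). A narrower band (down to a single-pixel line)
increases this bias; the default is a compromise between noise
suppression and geometric fidelity at the curved mask ends.

### Tethered-locus enrichment and densities

The three-circle measure is the standard tethering quantification: mean
intensities in equal circles at the tethered spot, a nuclear reference
position, and outside the cell; the outside mean is subtracted from both
others and the ratio `(spot - outside)/(nuclear - outside)` is returned.
Protocols alternate between a fixed nuclear reference circle and a
randomly chosen nuclear position; both amount to choosing the reference
centre. Particle densities are counts inside disjoint compartment masks
divided by compartment area in square micrometres.

### Spot detection

Puncta (PLA dots, HP1 foci, FISH/LacO spots, gold particles) are detected
by multi-scale Laplacian-of-Gaussian filtering over a geometric scale
ladder. Each scale's response is converted to robust-z units (offset from
the in-mask median, in MADs of the in-mask response) because each scale
has its own noise floor; detection takes spatial local maxima of the
cross-scale z maximum above `threshold_z = 7`, a default sitting between
the upper tail of the noise-maximum distribution on a smoothed field
(about z = 6 over 10^4-10^5 pixels) and the weakest matched-filter spot
response at signal-to-noise 5. Two further choices avoid systematic
artifacts: out-of-mask pixels are flattened to the in-mask median before
filtering, so the intensity step at the nucleus edge is not detected as a
ridge of blobs; and the per-spot scale estimate is the argmax of the raw
scale-normalized response, not of z (MAD shrinks with smoothing, which
would bias scale estimates upward). Greedy non-maximum suppression
removes a weaker detection closer than half the summed blob radii to a
stronger one, and centres are refined to sub-pixel precision by quadratic
interpolation. Raising the threshold never increases the count (the kept
set at a higher threshold is a prefix-stable subset).

A spot is classified *peripheral* when it falls in shell 1 of the 5-shell
equal-area partition — consistent with the positioning module, and giving
the interpretable chance rate of 20% — with a fixed distance-to-boundary
threshold as the alternative. External spot lists (TSV) can be imported
in place of the detector.

## Synthetic data

The generators emulate the study's two data modalities with recorded
ground truth and a mandatory seed (identical parameters and seed give
identical output; the caller's RNG stream is never disturbed):

* `simulate_peaks()` plants a subtelomeric fold exactly: each midpoint is
  subtelomeric with probability `fold x coverage`, else uniform over the
  complement. Lengths are geometric with a stated mean — simple, positive,
  memoryless — with a constant-length mode for exact-arithmetic and
  calibration tests.
* `simulate_mark_tracks()` draws per-peak joint overlap indicators from
  the 2x2 distribution with given marginals and odds ratio, materializes
  a mark under each positive indicator, and adds background intervals
  *calibrated so that a length-matched random window overlaps the track
  with the same probability as the planted marginal* (for equal interval
  lengths this makes base coverage about half the marginal — an extended
  window overlaps more than its midpoint does). Without this calibration
  the shuffled-background expectation would be systematically wrong and
  the null test miscalibrated. Planted indicators are exact for disjoint
  peaks; overlapping peaks share marks, which the generator reports (it
  returns realized indicators and warns about flips).
* `simulate_nucleus_image()` renders elliptical nuclei with a constant
  nucleoplasm level, a peripheral rim
  `A exp(-(d - d0)^2 / (2 sigma^2))` in boundary-distance `d` (offsetting
  `d0` emulates stains peaking at different depths — and puts the rim peak
  within reach of in-mask sampling when `d0` is at least a few pixels),
  Gaussian spots planted uniformly or at controlled radial area-quantiles
  (quantile `q` lands in shell `ceiling(qK)` by the same tie-break as the
  partition), and Gaussian or Poisson noise. Spots are planted with a
  minimum separation, emulating discrete puncta.

What the generators deliberately do **not** model: optics (no PSF beyond
the Gaussian spot profile, no chromatic shift), 3-D stacks (the analyses
quantify 2-D maximum projections, as such experiments typically do),
read-level sequencing data (peak calls are the input), nucleus shape
irregularity, and spatially structured backgrounds. Passing tests
therefore demonstrate the correctness and calibration of the estimators
under these idealized conditions, not robustness to every property of
real micrographs or real ChIP enrichment profiles.

## Problem sizes and numerical choices

The test and acceptance runs use desk-scale problem sizes chosen to make
the statistical checks sharp: interval-algebra oracle equivalence on 1,000
random instances over a ~20 kb toy genome; exhaustive exact-test
enumeration for all margins up to 20; fold recovery at 2,000 peaks and
permutation calibration with 400 null replicates at 199 permutations;
shell geometry on ellipse masks of ~2 x 10^4 pixels with 10^5 Monte-Carlo
points; detection benchmarks on 256 x 256 frames with 50 spots over 20
seeds; and co-occurrence calibration over 200 seeds of 1,000
constant-length peaks on a 10 Mb genome. Full-genome reanalyses
(deposited sequencing data, genome-wide peak calling) are beyond desk
scale; the package instead verifies that each estimator recovers planted
truths of the same character, up to a planted 9-fold subtelomeric
enrichment.

Other conventions: degenerate inputs raise errors rather than silently
degrading (empty peak sets, empty regions, all-zero tables, flat plateaus,
non-positive nuclear signal, overlapping compartments); out-of-mask points
and spots are counted and reported, never dropped silently; unknown
chromosomes in BED input are dropped with a warning by default (mirroring
the exclusion of unlocalized contigs) or rejected in strict mode; and all
report files carry the package version, seed, and a configuration hash, so
identical configurations reproduce byte-identical outputs.
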