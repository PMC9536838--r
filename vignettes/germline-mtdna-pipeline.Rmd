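---
title: "Quantifying germline mtDNA quantity and quality: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying germline mtDNA quantity and quality: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgcmt)
```

## The measurement problem

Animal germ lines inherit mitochondrial DNA (mtDNA) exclusively from the
mother, and mtDNA mutates faster than the nuclear genome. Two germline
mechanisms keep mutant genomes in check: a *bottleneck* that reduces the
per-cell genome count (amplifying stochastic drift of the mutant fraction
across offspring), and *purifying selection* that preferentially removes
mutant genomes. In *C. elegans* the entire germ line descends from two
embryonic primordial germ cells (PGCs) that stay quiescent until the first
larval (L1) stage, making them a tractable place to measure both
mechanisms — but the measurements are indirect: sorted-cell lysates read
out through droplet digital PCR (ddPCR), nucleoid counts read out through
3D fluorescence stacks, and all of it funnels through a hierarchy of
technical and biological replicates.

`pgcmt` implements that measurement chain as composable, tested pieces,
plus a generative model of the underlying biology so every analysis step
can be validated against known ground truth.

## The germline simulation model

The simulator treats a cell's mtDNA complement as two integer counts — a
wild-type class and a deletion class (`genome_pool()`), exactly two
haplotypes, no new mutations — and pushes it through the developmental
stages at which measurements are made:

1. **Reductive dilution** (`simulate_embryonic_dilution()`). The zygote
   pool passes through `n_embryonic_divisions` binary partitions with no
   replication; each genome independently joins one daughter with
   probability 1/2 (binomial segregation — the partition rule is a
   modeling choice; exact halving would understate segregation variance).
   One lineage is followed, and a final partition produces the two PGCs,
   so the expected per-PGC count is `n0 / 2^(divisions + 1)`.
2. **Proportional elimination** (`apply_proportional_removal()`). Lobe
   cannibalism and autophagy remove a fixed *proportion* of genomes —
   not a fixed number — so each genome is removed independently with
   probability `f`. Class counts remain independent binomials, which
   gives closed-form oracles and, importantly, leaves expected
   heteroplasmy untouched: these mechanisms are quantity control, not
   quality control.
3. **Selective elimination** (`apply_selective_removal()`). Purifying
   selection (PINK1-dependent in the biology) is modeled by separating
   "how many" from "which": the removal budget is the same
   `Binomial(total, f_select)` as a neutral mechanism, but victims are
   drawn without replacement with weight `w_select >= 1` on deletion
   genomes. At `w_select = 1` the step collapses to proportional removal
   — a testable reduction.
4. **Expansion to a set point** (`simulate_larval_expansion()`). Fed
   larval germline stem cells (GSCs) partition binomially at each
   division and then replicate genomes one at a time, each copy chosen
   with class weight `alpha_rep` (deletion genomes replicate
   preferentially when `alpha_rep > 1`), until the per-cell total reaches
   `set_point`. Cells at or above the set point never replicate and never
   cull — the set point is approached from below only, the simplest rule
   consistent with replication being balanced against division.

Genotype switches (`genotype_flags`) only ever *disable* a mechanism:
`nop_1` zeroes lobe cannibalism, `atg` zeroes autophagy, `pink_1` forces
`w_select = 1`.

### Default parameter values

The defaults are the study conditions of the wild-type germ line:

| parameter | default | meaning and basis |
|---|---|---|
| `n0` | 33,840 | whole early-embryo mtDNA copies |
| `h0` | 0 | wild type carries no deletion genomes |
| `target_per_pgc` | 1.2% of `n0` | measured per-PGC share of the embryo pool (the per-PGC volume share is also 1.2%, consistent with passive dilution) |
| `f_lobe` | 0.32 | embryonic 401 to late-embryonic 272 copies |
| `f_auto` | 0.19 | late-embryonic 272 to L1 220 copies |
| `set_point` | 200 | the actively maintained GSC copy number |
| `f_select`, `w_select` | 0, 1 | no selection without a deletion haplotype |
| `n_droplets`, `droplet_volume_nl` | 20,000, 0.85 | QX200-class droplet constants (instrument named, constants not printed; both configurable) |

The deletion-strain preset `sim_config_uadf5()` starts at `h0 = 0.48`,
switches on selection (`f_select = 0.2`, `w_select` calibrated, see
below) and gives the deletion a replicative advantage
(`alpha_rep = 1.3`) so heteroplasmy climbs back once bulk replication
resumes in GSCs — qualitatively matching the observed embryonic 48%,
L1 43.5%, L2 ~53% trajectory. `alpha_rep` is set once for a plausible
climb over two to three divisions and is not tuned further.

### Two calibrations, made once

**Integer divisions.** `log2(33840 / 401) - 1` is about 5.4, not an
integer. Rather than bend the per-division model, the division count is
rounded and the fractional remainder is applied as a single Bernoulli
thinning of the zygote pool, so the expected per-PGC count lands exactly
on target. The thinning models nothing mechanistic; it absorbs the
mismatch between an integer lineage depth and a continuous measured
fraction.

**Selection weight.** `calibrate_w_select(h_pre, h_post, f_select)`
solves the first-order approximation in which each deletion genome is
removed with probability `f w / wbar`, `wbar = h w + (1 - h)`. For the
embryonic-to-L1 drop of 48% to 43.5% at `f_select = 0.2` this gives
`w_select` of about 2.1. Sampling without replacement makes the realized
drop slightly smaller than the first-order target (by roughly half a
point at these pool sizes); the calibration is deliberately left
approximate and the tests assert the realized value within one point.

### Randomness and reproducibility

Every stochastic stage draws from its own stream derived from the master
seed by hashing a stage label (`derive_seed(seed, "dilution")`, ...), so
results are reproducible bit-for-bit and adding draws to one stage never
perturbs another. Weighted sampling without replacement is drawn by an
exponential race — each genome gets an `Exponential(weight)` lifetime and
the k shortest-lived are removed — which defines the same distribution
as sequential weight-proportional draws but vectorizes; the test suite
checks the implementation against an independent sequential-recursion
oracle.

## ddPCR quantification

A droplet generator partitions a reaction into ~20,000 ~0.85 nL droplets;
template molecules land in droplets as a Poisson process. With positive
fraction `p`, mean occupancy is `lambda = -ln(1 - p)` and concentration
follows by dividing droplet volume and multiplying the dilution back out
(`estimate_concentration()` reports copies per µL of *undiluted* lysate,
so dilution is handled in exactly one place). The confidence interval is
the delta-method normal approximation,
`SE(lambda) = sqrt(p(1-p)/n) / (1-p)` — standard practice at 20,000
droplets; an exact binomial inversion would be the natural extension
point if very low droplet counts ever mattered. A fully positive well is
an *error*, not a clipped value: the workflow dilutes specifically to
avoid saturation, so saturation means the dilution was mis-specified.

Technical replicates (wells are run in triplicate) merge by the
arithmetic mean of per-well concentrations, with a t-interval on the
replicate spread; per-well values are retained for the superplot layer.

## Copy number, ploidy, heteroplasmy

Per-cell copy number divides the mitochondrial template total by the
nuclear template total scaled by ploidy:
`mt_per_cell = mt_total * N / gdna_total`. The ratio cancels any common
scale, so concentrations can be used directly. Quiescent PGCs are
G2-arrested, hence `N = 4`. For cycling GSCs the ploidy is estimated
empirically: the starved-L1 4N state anchors an expected nuclear yield
per sorted cell, and `estimate_ploidy(actual, expected)` scales 4 by the
detected-to-expected ratio (the worked numbers 46/61 give 3.02,
"approximately 3"). Downstream arithmetic uses the *unrounded* estimate;
rounding first can inject up to ~17% bias, so the integer version exists
only for description. The expectation is an empirical anchor, not a
4N-theory prediction: sorted-cell lysates detect far fewer nuclear
copies than ploidy times cell count, and that detection efficiency is
carried as a single configurable constant (`gdna_efficiency`) with no
mechanistic claim.

Heteroplasmy is `100 * del / (del + wt)` from two single-target assays on
the same lysate. Stage-to-stage shifts are computed within paired
biological replicates (both stages always derive from the same adult
population) with the sign convention `shift = early - late`: a positive
shift means heteroplasmy dropped, i.e. selection acted. Shifts are taken
on biological-replicate values with technical replicates collapsed
first, matching the replicate hierarchy of the design.

One genuinely open point: whether the total-mtDNA amplicon detects
deletion genomes. The deletion lies outside that amplicon in the genome
schematic but this is never stated outright, so the generator exposes
`nd1_detects_deletion` (default `TRUE`) and the analysis makes no
assumption either way — copy number uses the total-mtDNA assay,
heteroplasmy uses the class-specific pair.

## Imaging measurements

All image operations work on 3D `[z, y, x]` arrays with anisotropic
voxels.

* **Thresholds** default to per-channel Otsu (the original manual
  ImageJ thresholds are unreported); every threshold is overridable and
  the values used are recorded.
* **Focus counting** smooths with a 3×3×3 box (single-voxel noise spikes
  otherwise masquerade as maxima), finds 26-connected local maxima
  inside the colocalization mask, floors candidates at an Otsu split of
  in-mask intensity, and suppresses candidates within a minimum
  separation — by default 3 voxels laterally and 1 axially, reflecting
  the coarser z-sampling. Because the reference parameters of the
  original plugin are unreported, absolute focus counts are validated
  against synthetic truth (recovery ≥ 95%, false positives ≤ 5% across
  an SNR sweep), not against published counts.
* **Acidification** uses the twofold rule: a region is acidified when
  its green/red ratio is at most half the network-wide ratio
  (inclusive ≤), with a 5-voxel minimum region size. The reference ratio
  includes any candidate region, so a region at *exactly* half the
  surrounding ratio computes to just above the threshold and is not
  flagged — the documented boundary behavior; detection requires
  genuinely deeper quenching. The categorical flag (any region present)
  is what feeds Fisher's exact test.
* **Manders M1** is the fraction of channel-A intensity in voxels where
  channel B exceeds threshold — bounded in [0, 1] by construction.
* **Volumes** use the stated closed forms: ellipsoid `4/3 π a b c` from
  measured semi-axes (whole embryos), sphere `4/3 π (d/2)^3` from a
  measured diameter (sorted cells). Both are checked against Monte-Carlo
  voxel integration to 0.5%.
* 3D connected-component labelling is hand-rolled (flood fill,
  26-connectivity): the available image libraries label components
  slice-wise in 2D only.

## Replicate statistics

The superplot discipline is enforced, not optional: technical replicates
are averaged within each biological replicate, groups are summarized by
the mean of biological means with SEM across biological means, and every
hypothesis test runs on biological-replicate means — technical
replicates never inflate n. SEM with a single biological replicate is
`NA`, never a silent pool of technical replicates. Unbalanced technical
replication does not reweight biological replicates.

Tests follow the conventions of the design: unpaired t tests for copy
number (embryos and larvae may come from different adult populations),
paired t tests for heteroplasmy (always the same population), explicit
declaration of one-tailed directions, Fisher's exact test for
categorical scores, and a paired t test on log-ratios as the
"paired-ratio" flavor for ratio readouts. No multiple-comparison
correction is applied by default — these are small hypothesis-driven
panels where type II errors are judged the greater risk — with an
optional Benjamini–Hochberg switch (`adjust_pvalues()`) for users who
disagree. Identical paired groups are reported as `t = 0, p = 1` rather
than erroring on zero variance.

## Validation problem sizes

The test suite validates at sizes chosen to bound Monte-Carlo error well
below the tolerances being asserted: partition-variance checks enumerate
pools up to 12 genomes exactly and use 4,000–6,000 replicates at 400
genomes; removal neutrality uses 2,000 replicates on a (200, 200) pool;
the ddPCR inversion sweep uses 500 wells of 20,000 droplets at each of
five occupancies from 0.05 to 2; end-to-end copy-number recovery runs 20
sorted-cell studies of 5,000 cells plus a germline-model run of 150
worms per biological replicate; the type-I-error check runs 2,000 null
shift studies; the imaging sweep uses 12 stacks across four
signal-to-noise ratios.

## What the generator does and does not emulate

The synthetic data carry the statistical structure the analysis assumes:
binomial segregation and thinning, Poisson droplet occupancy, triplicate
wells, paired stages within biological replicates, Gaussian spots on
anisotropic grids with truth annotations. They deliberately do **not**
emulate: fluorescence-amplitude distributions or "rain" (droplet inputs
are already-classified counts), duplex cross-talk (all wells are
single-target), sorter impurity or gating, spatial cell mechanics or
lobe geometry (cannibalism is count-level), PCR inhibition or
differential amplification efficiency, realistic point-spread functions
or depth-dependent attenuation. Passing tests therefore demonstrate that
the *analysis* is correct under the stated stochastic model, not that
the model captures every failure mode of real instruments; on real data
the unmodeled effects (amplitude thresholding, sorter purity, optical
aberration) are exactly where caution belongs.

## Known limitations

* The delta-method interval undercovers slightly at very low positive
  counts; an exact inversion is the noted extension point.
* The first-order selection calibration overshoots the weight needed for
  a target drop by a second-order term; it is documented and tested as
  approximate.
* Per-cell focus assignment requires user-supplied cell labels; no
  automatic segmentation is attempted.
* The simulator's two-class genome model cannot represent multi-allele
  heteroplasmy or de novo deletion formation.
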