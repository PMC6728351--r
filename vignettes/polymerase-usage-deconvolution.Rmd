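---
title: "Deconvolving replicative polymerase usage from ribonucleotide end counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving replicative polymerase usage from ribonucleotide end counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement and the model

Eukaryotic genomes are replicated by three polymerases with a canonical
division of labor: Pol ε extends the leading strand continuously, while the
lagging strand is built from Okazaki fragments primed by Pol α-primase and
extended by Pol δ. Strains carrying ribonucleotide-permissive polymerase
variants in a ribonucleotide-excision-repair-deficient background embed
excess ribonucleotides wherever the variant polymerase synthesized DNA;
cleaving at those ribonucleotides (RNase HII digestion followed by 5′-end
sequencing) turns each polymerase into its own genomic biomarker. This
package implements the computation that turns such strand-specific end-count
tracks into per-bin polymerase synthesis fractions, and the downstream
analyses of replication initiation and termination, on fully synthetic data.

The measurement model for the corrected end count `y` at bin `i`, strand
`j`, in strain `K` is

    y_{i,j,K} = w_{i,j} * sum_k s_{k,K} * f_{i,j,k}

where `f_{i,j,k}` is the fraction of synthesis by polymerase `k` (α, δ, ε;
the fractions sum to 1), `s_{k,K}` is polymerase `k`'s ribonucleotide
incorporation rate in strain `K`, and `w_{i,j}` is a multiplicative noise
factor that depends on position and strand but not on the polymerase
background. Three strain contrasts (one per variant), each sharing `w` and
`f` with the others, give three equations; eliminating `w` between strain
pairs yields two expressions for `f_α` that are linear in `f_δ`, written
with bilinear coefficients `A..F`, and setting them equal gives the closed
form

    f_δ = (CE − FB) / (FA − CD)

with `f_α` recovered by back-substitution, `f_ε = 1 − f_α − f_δ`, and `w`
from the ε-variant equation. `solve_fractions()` evaluates this per bin and
strand, vectorized. Two numerical guards apply: bins where
`|FA − CD|` falls below `1e-12` times the magnitude of its two terms are
flagged unsolvable (`NA`, never silently zero), and bins with any `y` below
a configurable coverage floor are emitted as missing. Missing bins propagate
through smoothing by renormalizing the moving average over observed bins
only.

A two-variant mode serves designs with only δ- and ε-variant strains (as in
fission yeast): with `f_α` lumped into `f_δ` the same elimination yields
`f_δ = −B/A`. `f_ε` — the only input to the DDAF — is unchanged wherever
true Pol α usage is absent, which the test suite verifies.

## Rate calibration and its identifiability limit

Incorporation rates are not fitted by least squares; they are read off from
calibration windows — regions replicated by forks from a single origin at
least 90% of the time, located with a Monte Carlo estimate of
leading-strandedness (`leading_strandedness()`, threshold configurable via
`select_calibration_windows()`). Where the top strand is always nascent
leading strand, the ε-variant strain's corrected end density equals
`s_ε-variant` directly; the complementary windows read out the lagging
mixture. Before extraction, each variant strain is rescaled so that windows
synthesized there by wild-type polymerases match the wild-type strain
(leading windows for the δ/α variants, lagging windows for the ε variant).

Window means identify `s_ε`, `s_ε-variant` and the three lagging mixtures
`h·s_α + (1−h)·s_δ` (and variants), where `h` is the Pol α head fraction of
an Okazaki fragment. They cannot separate `s_α` from `s_δ`: pure Pol α
tracts do not exist at calibration scale. `estimate_rates()` therefore takes
two priors — `head_fraction` (default `primer_len/okazaki_len` of the
generating program) and the wild-type ratio `alpha_delta_ratio`
(`s_α/s_δ`, default 8) — and documents them in its output. Sensitivity is
mild for `f_ε` (which dominates the DDAF) and strongest for the split
between `f_α` and `f_δ` on lagging strands.

Because the 90% threshold leaves some mixed provenance in the windows, the
rates are slightly underestimated and solved `f_ε` can exceed or undershoot
1. `rescale_epsilon()` applies the standard correction: divide `f_ε` on both
strands by the genome-wide maximum of its smoothed track (1 kb default).
The rescale is linear, so it changes neither positions nor shapes of DDAF
peaks; the scale factor is carried as provenance on every DDAF track.

## The DDAF and peak quantification

The deviation from the expected Pol δ/α fraction of synthesis is

    DDAF_i = 1 − f_{i,top,ε} − f_{i,bottom,ε}

Canonical labor gives 0; both strands synthesized by Pols δ and α give +1;
both strands by Pol ε give −1. Meta-profiles
(`aggregate_at_anchors()`) align the DDAF at oriented anchors — origins
oriented by their consensus-sequence strand, or predicted collision points —
reversing minus-oriented rows; cells beyond a chromosome end or beyond
per-anchor truncation limits (the member origins of a termination tract)
are missing and excluded from the mean curve.

Peak areas (`peak_area()`) subtract a baseline estimated from the outer 15%
of bins at each end of the curve (the middle of the 10–20% convention;
configurable). This baseline is deliberately aggressive; the resulting
over-subtraction is corrected downstream by regressing per-origin areas on
origin efficiency (`tract_length_fit()`, ordinary least squares) and
reading the tract length of an ideally efficient origin off the
extrapolated area at efficiency 1. Areas integrate signed deviations, so
slightly negative areas at inefficient origins are expected and permitted.

## The synthetic replication program

`simulate_replication()` is the package's ground-truth generator and also
the engine behind the leading-strandedness estimate. Per iteration, each
origin draws a firing time from Normal(`t_fire × s_t`, `sigma_t`); an
origin overrun by a fork before its drawn time is passivated (ties count as
fired — a measure-zero event under any `sigma_t > 0`). Forks move at a
single global velocity `v_f`; adjacent fired origins collide at the
midpoint offset by half the firing-time difference times `v_f`; forks
reaching a chromosome end terminate without a collision. Polymerase
identity is assigned per nucleotide:

* each leading strand starts with one Okazaki-like initiation unit of
  length `l_init/2` — a Pol α head of `primer_len` (25 bp default) and a
  Pol δ body — before Pol ε takes over. `l_init` is the *per-origin total*
  (180 bp default, roughly one Okazaki fragment), so a fully efficient
  origin contributes `l_init` of non-ε leading-strand DNA and its
  unsmoothed DDAF peak area equals `l_init` exactly;
* within `l_coll` (4.6 kb default) of a collision point the leading strand
  switches from Pol ε back to Pol δ, while Okazaki fragment synthesis on
  the lagging strand continues unperturbed — the favored termination
  scenario; alternative scenarios are not implemented;
* lagging strands are represented by the expected per-nucleotide Okazaki
  composition (`primer_len/okazaki_len` Pol α, the rest Pol δ) rather than
  by sampling random fragment phases; the iteration average converges to
  exactly this value and only bin-level tracks are consumed. Pol
  α-synthesized primer DNA at leading-strand 5′ ends is included
  proportionally the same way.

Iterations are averaged into 50 bp bins by exact integration of the
piecewise-constant per-iteration composition (no nucleotide-resolution
arrays are materialized), which keeps a 5 Mb genome at 800 iterations
within seconds. Defaults for time parameters follow the fast-clock presets
(`v_f` 6 kb/min, `sigma_t` 2.6 min, `s_t = 1`); the slow-clock preset
(`s_t = 3.75`, `v_f` 1.6 kb/min, `sigma_t` 9.75 min) is available via
`termination_presets()`. Time rescaling — multiplying all firing times and
`sigma_t` by `s_t` while dividing `v_f` by `s_t` — is an exact symmetry of
the firing process under a shared random stream, and realized efficiencies
are invariant under it.

`forward_model()` turns ground-truth fractions into end-count samples:
expected treated counts are `depth × (w × Σ s_k f_k + background)` with `w`
drawn log-normal once per bin/strand and shared across strains, treatments
and replicates; untreated controls carry only the background; counts are
Poisson; restriction-site standards receive `site_strength × depth` expected
counts scaled by each sample's log-normal relative depth. The generator
emulates replicate scatter, library-size variation, position-specific
efficiency bias and shot noise. It does not emulate mappability gaps,
repeat-driven multi-mapping noise, chromatin effects on fork speed, or
replication stress and restart — so green tests here demonstrate the
correctness of the computation under the stated model, not robustness to
every artifact of real sequencing data.

## Normalization and background correction

`normalize_by_sites()` follows the restriction-site internal-standard
scheme: per site, the geometric mean of counts across all samples; per
sample, the factor is the median over sites of count/geometric-mean; sites
with a zero count in any sample are excluded outright (no pseudocounts).
One algebraic property deserves note: scaling one of `n` samples by `c`
multiplies every per-site geometric mean by `c^(1/n)`, so *every* sample's
normalized track scales by exactly `c^(1/n)`. Per-sample absolute levels
are therefore only defined up to a common factor; all cross-sample
structure is exactly invariant, and the solved synthesis fractions are
exactly invariant because the `A..F` coefficients are bilinear in `y` (a
global scale cancels in the ratio) and `w` absorbs the rest. The acceptance
suite asserts precisely these invariances. Replicates are averaged after
normalization and before background subtraction; corrected counts are
floored at 0 (negative ribonucleotide densities are unphysical), with the
raw difference retained in an attribute because the deconvolution algebra
tolerates it.

## Origin calling

Origins appear as abrupt, strand-concordant transitions in `f_ε`: up on the
top strand (lagging→leading, left to right) and down on the bottom strand.
`call_origins()` computes, at each bin boundary, the difference between the
mean over the next window and the mean over the previous window (1 kb
default), takes local extrema of that statistic exceeding `min_shift` (0.1
post-rescale) on both strands with opposite signs, and pairs them within
two windows; the call position is the midpoint of the paired boundaries.
Calls rank by shift height, which on clean data increases with origin
efficiency, and the ranking is invariant under the `f_ε` rescale. A mask of
non-unique regions (telomeres, transposons) can drop calls; coverage-floor
filtering upstream is the guard against steep transitions caused by thin
data rather than origins.

## Fitting the termination model

`simulate_collisions()` is the lightweight simulator used for inference:
it tracks firing, passivation and collision points only, accumulates the
collision-tract density (fraction of iterations each bin lies within
`l_coll` of a collision; overlapping tracts in one iteration count once),
and reports per-origin efficiency as 1 − overrun fraction. The density
integrates to twice `l_coll` per collision, and the sum of efficiencies
estimates the mean number of origins firing per S phase.

Fitting proceeds exactly in the staged order: first `fit_velocity()` scans
`v_f`, scoring the RMSD between predicted collision peaks (per-tract mean
collision positions) and observed DDAF peak positions, pairing each
predicted peak with the nearest observed peak inside the same inter-origin
tract and charging unpaired peaks a penalty capped at half the tract
length; a cubic fit locates the interior minimum (flagged if none). Then
`fit_sigma_lcoll()` scans a `sigma_t` grid per candidate `l_coll`, fits
each R² curve with a cubic to get the per-`l_coll` optimal `sigma_t`, fits
the exponential link `sigma_t*(l_coll) = a·e^{b·l_coll}` on the log scale,
locates the optimal `l_coll` from a cubic through (`l_coll`, max R²), and
takes `sigma_t` at that optimum from the exponential. A confirmation run at
the joint optimum (1000 iterations; scans use 500) must reproduce the
polynomial prediction within 2% or the result is marked unverified.

Three numerical choices here were genuinely open and matter:

* **Fit quality is R² on the absolute scale** — the coefficient of
  determination `1 − SS_res/SS_tot` of the simulated density against the
  observed DDAF over inter-origin tracts (a 2 kb margin around each origin
  is excluded so initiation peaks do not leak in). Both tracks are
  per-iteration probabilities on a common scale, and the density
  *amplitude* is what identifies `l_coll`: under fast-clock dynamics the
  collision-position spread (`v_f·sigma_t/√2` ≈ 11 kb) dominates the tract
  width, so after any per-track standardization the shape alone is nearly
  flat in `l_coll` and the scan has no usable interior maximum.
* **Identical smoothing on both tracks** (1 kb default) before scoring: a
  longer collision tract mimics a smoothing kernel, so smoothing only the
  observed track biases `l_coll` upward.
* **Common random numbers**: all scan points share one random stream, so
  objective differences across the grid reflect the parameters rather than
  sampling noise; without this, grid-to-grid Monte Carlo scatter in R²
  (~0.1–0.3% at 500 iterations) exceeds the curvature of the `l_coll`
  objective. The verification run deliberately uses an independent stream.

## Study designs shipped with the package

The analysis scripts run three studies whose sizes were chosen to resolve
each question:

* the **end-to-end pipeline** runs on a 2 Mb chromosome with 12 origins of
  mixed firing times (the shipped YAML program), 300 ground-truth
  iterations, three replicates per strain × treatment at ~80 counts per
  50 bp bin on leading strands;
* the **initiation study** uses 30 origins on separate 60 kb chromosomes,
  each paired with an early pacemaker origin whose fork passivates it with
  a programmed probability spanning 0.1–0.995 (placing the target's mean
  firing time at `d/v_f − √2·sigma_t·Φ⁻¹(e)`), 400 iterations, noise off.
  The fixture keeps `l_coll` minimal (200 bp): conditional on a
  barely-firing origin, the collision with the passivating fork lands at
  that origin, and paper-scale collision tracts would contaminate the
  ±1 kb origin windows with termination signal — this study isolates
  initiation, and termination has its own fixture;
* the **termination study** uses two 2.5 Mb chromosomes with 15 origins
  each (28 inter-origin tracts) at the fast-clock truth (6000 bp/min,
  2.6 min, 4.6 kb), an observed DDAF built from 800 ground-truth
  iterations, scans at 500 iterations and verification at 1000.

## Known limitations

* `s_α` and `s_δ` are identified only through the head-fraction and rate
  ratio priors; mis-specifying those shifts the α/δ split on lagging
  strands (not `f_ε` or the DDAF).
* The origin caller assumes transitions are isolated at the smoothing
  scale; origins closer than about one window merge into a single call.
* `l_coll` is intrinsically weakly identified when `v_f·sigma_t` is large
  relative to it; the absolute-scale R² restores identifiability under the
  shipped conditions, but very noisy observed tracks will widen the
  confidence one grid step either way.
* Chromosome ends terminate forks without collision tracts; telomere
  biology is out of scope.
* The per-sample normalization scale is defined only up to a common global
  factor (see above); any analysis consuming absolute normalized counts
  rather than ratios or fractions must account for this.
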