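---
title: "Counting replicons: models, protocols and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting replicons: models, protocols and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repliconscope)
```

## The question the package answers

During S-phase a mammalian genome is duplicated by tens of thousands of
replicons — chromosome segments each replicated from a single origin-firing
event by two diverging forks. Under the microscope, DNA synthesis
concentrates in discrete nuclear replication foci (RFi). For decades the
number of RFi visible at conventional resolution (several hundred) was far
below the number of simultaneously active replicons predicted from molecular
measurements, so each focus was interpreted as a "replication factory"
processing multiple replicons. Super-resolution (3D-SIM) imaging raises the
observable focus count to several thousand, which makes a direct
quantitative comparison possible. The package implements that comparison:

* **Total replicons** `N_tot = GS / IOD` — genome size over the average
  inter-origin distance.
* **Replicon lifetime** `tau = IOD / (2 RFS)` — the time two forks need to
  close an average inter-origin gap.
* **Limiting-factor reuse** `T_S / tau` — how often an initiation factor is
  recycled.
* **Forks in parallel** `GS / RFS / T_S`, and half as many bidirectional
  **replicons in parallel**.
* **Replicons per focus** — replicons in parallel divided by the counted
  number of RFi. A value near 1 means a super-resolved focus corresponds to
  a single replicon.

Uncertainty of the quotient is propagated with the first-order (Gaussian)
variance formula for products/quotients,
`MSE = |q| * sqrt(sum((sigma_i / x_i)^2))`
(`propagate_mse()`), verified in the test suite against a Monte-Carlo
sampling oracle. With the reference HeLa Kyoto and C2C12 measurements that
ship in `example_parameters()`, the chain yields quotients of 0.92 and 0.77
(the unit tests assert both, and `scripts/acceptance.R` recomputes them).
Note that first-order propagation from the tabulated standard errors gives
an MSE near 0.07; the reference analysis this workflow mirrors reports 0.2
and 0.3, values not recoverable from any obvious combination of the
tabulated dispersions. The package reports what it computes and does not
hard-code the published uncertainty.

Every input modality has a synthetic generator with exact ground truth, so
the full chain is testable without microscope data.

## Focus counting

Two deterministic protocols are implemented.

**Conventional resolution** (`count_confocal_rfi()`): slice-wise mean filter
(disk radius 1.5 px, 9 pixels) → global min–max normalization → slice-wise
local maxima with a prominence tolerance (default 0.1 of the normalized
range) → Gaussian "artificial focal object" reconstruction around each
marked maximum (sigma 1 px) → 26-connected 3D component counting. Maxima
found in adjacent z-slices at the same lateral position merge into one 3D
object, which is how a slice-wise maxima search yields a 3D count.

Two details deserve justification:

* The maxima search follows the ImageJ flood rule (candidates processed in
  decreasing intensity; a candidate whose tolerance region touches a higher
  maximum's territory is merged), plus one addition: a candidate must also
  rise more than the tolerance above the stack minimum. Without the floor,
  every object-free noise slice contributes its global maximum as a spurious
  mark. The floor only suppresses marks that are indistinguishable from
  background.
* The counting threshold defaults to half the reconstructed peak of an
  isolated maximum (analytically `single_marker_peak(sigma)`), so a single
  mark always survives thresholding and the minimum object size (4 voxels,
  chosen to suppress single-voxel noise; not prescribed by the source
  protocol).

**Super-resolution** (`count_sim_rfi()`): automatic background removal by
the triangle (Zack) threshold on a 256-bin intensity histogram →
26-connected labelling → minimum-size filter → marker-controlled 3D
watershed separation of touching foci → count. The triangle construction is
tested against an exhaustive point-to-line-distance oracle on random
histograms.

The separation step (`separate_touching_objects()`) floods the inverted
smoothed intensity from h-maxima markers (domes of relative height `h_rel`,
default 0.1 of the smoothed dynamic range). The commercial tool used in the
original workflow is unpublished; marker-controlled watershed was chosen
because it is deterministic and satisfies the contract the analysis needs:
it never merges objects (flooding cannot cross component boundaries) and a
single convex blob, having one h-maximum, is never split. Components with
no detectable internal structure are kept unchanged.

Both protocols operate on the voxel grid without resampling; voxel sizes
travel as metadata only. Stacks are assumed to be cropped to one nucleus —
interactive cropping and nucleus segmentation are out of scope.

`resolution_ratio()` forms per-cell super-resolution/conventional count
ratios, the pooled ratio (sum over sum) and a combined value (mean of the
per-cell ratios and the pooled ratio) with its s.d., mirroring how
per-cell and pooled population ratios are compared in practice.

## Synthetic image stacks

`generate_nucleus_stack()` places point-source foci inside an ellipsoidal
nucleus (default 16 x 12 x 6 um) and renders each as an anisotropic
Gaussian PSF blob plus background, Poisson photon noise and Gaussian read
noise. Three optical profiles are built in:

| profile | lateral / axial PSF sigma (nm) | voxels (nm) |
|---|---|---|
| `confocal` | 110 / 300 | 104 x 104 x 500 |
| `widefield_decon` | 90 / 250 | 40 x 40 x 125 |
| `sim` | 50 / 140 | 40 x 40 x 125 |

The voxel sizes are the acquisition grids of the emulated instruments; PSF
widths are not printed in the protocols the profiles emulate, so they were
chosen once as plausible Gaussian equivalents that preserve the empirical
resolution ordering (sim < deconvolved wide-field < confocal) and make the
~5x conventional-to-super-resolution count ratio regime reachable. All are
configurable. Per-focus brightness has a free heterogeneity parameter
(default CV 0.2) because focus intensity distributions per S-phase stage
are not specified anywhere; integrated intensity defaults to 5000 photons
over a background of 10 photons/voxel, a regime where neither protocol is
photon-starved.

Placement options matter for what a test can claim:

* *Minimum separation* is enforced with an ellipsoidal exclusion zone:
  lateral radius `min_sep_nm`, axial radius defaulting to three times that.
  Axial optical resolution is roughly threefold worse than lateral, so an
  isotropic minimum distance would still allow axially fused pairs and
  "exact recovery" tests would fail for reasons unrelated to the protocol.
* *Clustering* uses parent/offspring placement (a Thomas-process stand-in):
  cluster centres with their own minimum separation, members on a small
  ring (or ball) of configurable radius. The ring layout with ~220 nm
  radius fuses into one blob at confocal resolution while remaining
  separable at SIM resolution, which is exactly the geometry needed for
  merge-factor experiments.

The generator does **not** emulate chromatin texture, S-phase pattern
morphology, depth-dependent aberrations, SIM reconstruction artefacts or
non-uniform background. A green count-recovery test therefore establishes
that the protocol implementation is correct on PSF-limited data with known
truth — not that real late-S-phase nuclei, where dense clustering degrades
separability, are counted exactly.

`render_foci_stack()` re-renders the same ground truth under another
profile, which is what makes cross-resolution comparisons on identical
geometry possible.

## DNA fibre model

`generate_fibre_set()` emulates dual-pulse labelling (two consecutive
30-min pulses) of DNA combed at 2 kbp/um into 250–500 kbp fibres. Origins
fire at the start of the first pulse; each origin's two forks run at
per-fork speeds drawn from a truncated normal; converging forks of adjacent
origins terminate where they meet; positions replicated in the first/second
pulse carry the `pulse1`/`pulse2` label; fibre ends truncate segments,
which are then flagged censored.

Estimators work purely from the segment table:

* `estimate_rfs()` uses second-pulse segments adjacent to first-pulse
  signal on exactly one side (the free-running fork signature; fused
  converging forks show first-pulse signal on both sides) and not touching
  a fibre end. Speed is segment length x stretch / pulse duration.
* `estimate_iod()` calls origins as first-pulse segments flanked by
  second-pulse signal on both sides (the bidirectional signature), places
  each origin at the first-pulse midpoint and measures centre-to-centre
  distances. Whether one-sided flanking should also count is genuinely
  ambiguous in practice, so it is exposed as `flanked_only`.

Two modelling decisions interact with parameter recovery. First, spacings
that would fuse two first-pulse tracks before the end of the first pulse
are redrawn: such origin pairs are uncallable on a real fibre as well, and
keeping them would only create blind merges. Second, because of this
conditioning and of fibre-end censoring, the realized mean of measurable
spacings exceeds the nominal distribution mean (for the C2C12-like setting,
nominal 161.7 kbp with s.d. 100.3 kbp, the lower truncation lifts the
realized mean by roughly 15–20%), and fork selection slightly favours
slower forks (fast forks terminate more often). The generator therefore
reports the realized means over measurable pairs and clean forks
(`true_iod_mean`, `true_rfs_mean` attributes) as the recoverable ground
truth, and recovery tests compare estimators against those. This mirrors
the real assay: the measured spacing distribution is already conditioned on
the pattern being resolvable.

Descriptive statistics (`summarize_values()`) use the n−1 sample s.d.,
s.e.m. = sd/sqrt(n) and a 1.96 multiplier for the 95% CI half-width — the
multiplier is consistent with the reference tables this mirrors
(s.e.m. 17.2 → CI 33.6; s.e.m. 0.12 → CI 0.23). `sliding_average()`
implements the sample-size diagnostic; the convergence flag requires the
final quarter of running means to stay within 5% (default) of the final
mean, a threshold chosen once since the original criterion is not stated.

## Genome sizing

`generate_dna_histogram()` builds a channel/count histogram with a
reference G1/G0 peak (non-cycling splenocytes, default channel 36), the
sample G1 peak at `reference x relative_amount`, an S-phase plateau and a
G2 peak at twice the sample G1 position. Peaks are Gaussian with a
configurable CV; cells are drawn individually so fitting uncertainty
scales as 1/sqrt(n). Because integer channel binning adds ~1/12
quantization variance, draws use a correspondingly narrower continuous
s.d., making `peak_cv` the CV actually measured on the histogram (the <2%
quality bound for reference histograms is asserted on the measured value).

`fit_g1_peaks()` does least-squares Gaussian fits inside user-annotated
channel windows; automatic multi-peak deconvolution of the full cell-cycle
histogram is deliberately not attempted. The conversion chain is
`pg = ratio * 7 / (1.06 * 1.016)` (diploid human DNA mass, human/mouse
genome-size correction, female/male correction) and `Mbp = pg * 978`. The
formula is reverse-engineered to reproduce the reference genome-size table
within 0.3%; the exact order/direction of the two correction factors cannot
be uniquely recovered from that table (0.2–0.3% residuals under every
ordering), so all constants are configuration, not code.

## Cell-cycle durations

`generate_timelapse_labels()` emits per-frame stage labels in the
biological order M → G1 → Se → Sm → Sl → G2 at a 15-min frame interval,
with G1 and G2 frames emitted as `homogeneous` (a homogeneous PCNA
distribution cannot be staged from a single frame).
`disambiguate_homogeneous()` resolves them from temporal context: runs
after M (or before S) are G1, runs after S (or before M) are G2; runs with
no informative neighbour are flagged unresolved rather than guessed.

Frame rounding is half-up; when S sub-stages derive from one pooled S
duration, the rounded total S frame count is preserved and distributed by
largest remainder (independent rounding of thirds can inflate S by up to
1.5 frames, enough to break one-frame-interval round-trip recovery).
Transition frames belong to the later stage. Cells observed for less than
a full cycle contribute only stages whose runs are bounded on both sides
within the observation (`complete_only`), which reproduces the differing
per-stage n seen in real tracking data. Per-cell stage durations default to
the population means with randomness only in the starting phase; the
round-trip contract (each stage recovered within one frame interval at
n = 16–30 cells) is about rounding and disambiguation, not biological
variability, which can be layered on separately.

Doubling time is reported two ways: the sum of per-stage means and the
per-cell full-cycle mean. For the reference human measurements the stage
means sum to 23.0 h while the directly measured doubling time is 22.6 h —
the two differ in real data because stage means are computed over partially
overlapping cell subsets, so both are exposed.

## Firing-schedule simulation

`simulate_firing_schedule()` computes the time-averaged number of
simultaneously active replicons for `n_total` replicons of lifetime `tau`
over an S-phase of length `T_S`, under synchronous waves (waves of size
`n_total * tau / T_S` firing once per lifetime) or uniform asynchronous
activation. Both modes converge to the closed form `n_total * tau / T_S`;
the tests assert agreement within 1% and with the replicons-in-parallel
value from the summary chain. This is the quantitative content of the
claim that sequential-synchronous and asynchronous origin firing give the
same average number of parallel replicons.

## Numerical and I/O choices

* All generators draw through an internal seeded-RNG wrapper and are pure
  functions of their arguments; the caller's RNG state is untouched.
* Watershed flooding and maxima searches break ties deterministically
  (insertion order / linear voxel index), so label maps are reproducible
  voxel-for-voxel.
* Integer rounding (total replicons, reuse cycles) happens only at
  reporting; intermediate quantities keep full precision. The tabulated
  reference intermediates are themselves printed from unrounded inputs, so
  agreement is asserted within 0.2% rather than exactly.
* Stacks are exchanged as uncompressed 32-bit-float multi-page TIFFs with a
  JSON sidecar (`voxel_xy_nm`, `voxel_z_nm`, `modality`). No TIFF library
  is available in the target R installation, so a minimal baseline-TIFF
  reader/writer is implemented and round-trip tested (and was validated
  against an independent TIFF implementation during development). Fibre
  tracks, histograms and time-lapse labels use plain CSV.
* Degenerate inputs fail loudly: constant stacks cannot be normalized or
  thresholded, single-bin histograms cannot be triangle-thresholded,
  n < 2 has no sample s.d., a zero IOD/RFS/T_S has no derived quantity.

## Known limitations

* Optics are Gaussian-PSF stand-ins; no physical SIM reconstruction, no
  deconvolution modelling, no chromatic or depth effects.
* The fibre model fires all origins at the pulse start; firing-time
  spread within the labelling window is not modelled (it mostly trades
  measurable pattern frequency against track cleanliness).
* Late-S-phase clustering regimes where separation genuinely fails are
  exposed only as simulation experiments, not asserted constants.
* Intra-S-phase variation of RFS and IOD is out of scope throughout.
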