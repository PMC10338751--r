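---
title: "Log-file QA for pencil-beam scanning proton therapy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Log-file QA for pencil-beam scanning proton therapy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotqa)
```

## The QA model

A pencil-beam scanning (PBS) proton field is a sequence of energy
layers; each layer is a set of spots, and each spot carries a nominal
energy (one of 96 discrete machine levels between 69.4 and 221.3 MeV),
a lateral position (X, Y) at isocenter, an MU weight and a Gaussian
lateral profile. The record-and-verify log reports, per delivered spot,
its actual position, MU and (per layer) the monitored size. `spotqa`
treats both the plan and the log as flat spot tables (tibbles) and
verifies three physical quantities per spot or layer.

**Position.** The deviation of spot *i* on one axis is
$D_i = x^{del}_i - x^{plan}_i$. Within a layer of $N$ spots this is
decomposed as

$$\mathrm{sys} = \frac{1}{N}\sum_{i=1}^{N} D_i, \qquad
  \mathrm{rand}_i = D_i - \mathrm{sys},$$

so $D_i = \mathrm{sys} + \mathrm{rand}_i$ holds identically and
$\sum_i \mathrm{rand}_i = 0$ by construction. The systematic term is the
block shift of the whole layer from its planned centroid (steering or
calibration effects); the random term is the per-spot scatter about that
centroid. The decomposition is also the generative model of the
simulator, which is what makes parameter recovery a meaningful closed
loop: errors are *injected* as one systematic draw per layer plus
independent jitter per spot, and the analysis recovers exactly those
components.

**MU.** Delivered minus planned MU per spot, checked against an absolute
tolerance, with the percent difference (relative to planned MU) also
reported. The vendor's actual alarm and abort levels are proprietary, so
the MU tolerance here is configuration only; its default of 0.001 MU is
a placeholder a site must override, not a clinical constant. The
deliverable band (0.003 to 5 MU per spot) is checked as a validity rule
on any spot table.

**Size.** The spot-position monitor reports one-sigma Gaussian widths.
Delivered sigmas are averaged per layer and compared with the
commissioning baseline at that energy and gantry angle, with a relative
tolerance (default ±10%). Sizes are treated as a per-layer quantity
because that is the granularity at which the monitor verifies them.

### Tolerances and defaults

| parameter | meaning | default | unit |
|---|---|---|---|
| `pos_systematic_mm` | max layer block shift | 1.0 | mm |
| `pos_random_mm` | max per-spot residual | 1.0 | mm |
| `size_percent` | max layer size deviation vs baseline | 10 | % |
| `mu_abs` | max per-spot MU difference (placeholder) | 0.001 | MU |
| `mu_min`, `mu_max` | deliverable MU band | 0.003, 5 | MU |

The random-error tolerance is applied to each residual individually
rather than to a per-layer maximum; the per-spot reading is the stricter
of the two and matches the per-spot definition of the residual.

## Pairing plan and log

Layers are matched by index with an exact match required on the nominal
energy printed to 0.1 MeV — both sides originate from the same layer
definition, so an energy tolerance would only mask bookkeeping errors.
Spots within a layer are matched by delivery order. A beam hold can
split one planned spot into two consecutive log rows at the same
position (delivery resumes with the remaining MU); when the delivered
layer has more rows than the planned one, consecutive rows whose
positions agree within 0.01 mm are merged (MU summed, sizes MU-weighted)
before pairing. Merging is restricted to *consecutive* rows and only
engages on a count surplus, because resumed partial spots are delivered
back-to-back while coincident planned spots are legal. Nearest-neighbour
matching was rejected outright: it can silently absorb exactly the gross
positional errors the QA exists to catch. Any remaining mismatch is an
error naming the field, layer and counts, never a silent drop.

## Energy to water-equivalent range

The range check converts nominal energy to the continuous slowing-down
(CSDA) range in liquid water using an embedded reference table
(`inst/extdata/proton_water_csda_range.csv`, 10–250 MeV). Between nodes
the conversion uses a local power law $R = aE^p$ through the bracketing
entries — linear interpolation in log–log space, the conventional way
range tables are interpolated. A single global power-law fit was tried
and discarded: the effective exponent drifts from about 1.73 to 1.80
across the clinical domain, biasing mid-range energies by 1–2%, while
the piecewise form is exact at the nodes and reproduces 9.8 cm at the
fleet-mean 114.4 MeV. The valid domain is 60–230 MeV; outside it the
function raises a domain error rather than extrapolating.

## The synthetic-data generator

The generator is first-class, tested code; it emulates the *fleet
conditions* of the modelled three-room center (two interchangeable half
gantries G1/G2, one fixed room with standard and micro-beam modes):

* **Energies** are drawn from a normal distribution with mean 114.4 and
  SD 26.4 MeV, snapped to the 96 machine levels, unique per field,
  delivered high to low.
* **Spot MU** follows a lognormal moment-matched to mean 0.010 and SD
  0.009 MU, clipped to the deliverable band [0.003, 1.015] MU. The
  lognormal reproduces the hard minimum and strong right skew of
  clinical MU histograms; clipping shifts the mean by well under the
  0.001 MU calibration margin.
* **Spot positions** sit on a rectangular grid (6 mm pitch) with ±1 mm
  uniform jitter, stored to 0.001 mm like every position in the package.
* **Delivery errors** are the generative inverse of the QA
  decomposition: per layer one systematic shift draw per axis (SDs
  0.189/0.175 mm X/Y), per spot independent jitter (0.049/0.044 mm) and
  MU noise (2.0e-4 MU), per layer one size deviation per axis
  (0.131/0.166 mm) about the commissioning baseline. Mean offsets
  default to zero; a constant machine bias term is available but off by
  default, since observed nonzero mean offsets cannot be distinguished
  from convention without access to the machine.
* Every draw is recorded in a ground-truth object, and all randomness
  flows from one seed through a locally scoped RNG — the global random
  state is never touched.

**The synthetic commissioning baseline.** No public sigma table exists
for the modelled machine, so `synthetic_size_baseline()` provides a
synthetic stand-in: smooth monitor-plane one-sigma sizes falling from
about 13 mm at 69.4 MeV to about 9 mm at 221.3 MeV, with a small X/Y
asymmetry and a mild gantry-angle modulation emulating steering-magnet
effects. The ~10 mm scale was chosen from a consistency argument: on
the modelled system the ±10% size tolerance and the observed sub-±1 mm
size deviations are commensurate, which places baseline sizes near
10 mm at the monitoring plane. It also makes the default size-deviation
SDs (0.131/0.166 mm) sit 5–8 standard deviations inside the 10%
tolerance, so the simulated fleet reproduces the zero-flag record of
the clinical system rather than contradicting it.

**What the simulator does not capture.** Errors are injected
statistically, not mechanistically: no nozzle optics, scattering,
interlock timing or beam-hold logic is modelled, error draws are
Gaussian with no heavy tails or drift over calendar time, and MU noise
is independent of spot weight. Passing tests therefore demonstrate that
the *analysis* is correct and self-consistent, not that real deliveries
behave this way.

## Dose reconstruction and gamma analysis

The reconstructed ("delivered") plan is the original plan with each
spot's position and MU replaced by the logged values. Dose comparison
uses a 2D planar surrogate at the isocenter plane: each spot contributes
`mu` times a normalized bivariate Gaussian, so a spot's map integrates
to its MU and the map is exactly linear in MU. This deliberately stands
in for a treatment-planning-system recalculation on patient CT, which is
out of scope; consequently all dose-level acceptance is property-based
(identity deliveries pass at 100%, linearity and normalization are
exact) rather than anchored to patient DVH values.

Gamma analysis is *global*: dose differences are normalized to the
reference-map maximum (the common clinical QA convention), pixels below
10% of that maximum are excluded, and each evaluated reference pixel
takes the minimum generalized distance

$$\gamma(\mathbf r) = \min_{\mathbf r'}
  \sqrt{\frac{\Delta D(\mathbf r, \mathbf r')^2}{(3\%\,D_{max})^2} +
        \frac{|\mathbf r'-\mathbf r|^2}{(3\,\mathrm{mm})^2}}$$

over a search disc of radius `3 * dta` sampled on a fixed lattice of
step `dta / 10`, with the evaluated dose bilinearly interpolated at
each offset. The fixed lattice is a deliberate numerical choice: it
makes the optimized implementation and an exhaustive brute-force search
agree to floating-point precision, because both minimize over the same
finite candidate set. Two consequences are worth knowing. First, gamma
is monotone in the dose criterion exactly (the lattice is unchanged),
but monotone in `dta` only up to the lattice resolution, since changing
`dta` rescales the candidate set; the tests assert exact monotonicity
for dose and resolution-bounded monotonicity for distance. Second,
reference and evaluated grids must share geometry, which is what
`fluence_map(..., grid = )` produces.

## File formats

The native log format of clinical record-and-verify systems is
proprietary, so the package defines an open CSV dialect (versioned,
exact header match) carrying per-spot MU, position and size plus session
metadata; a plan CSV dialect; and a baseline CSV. All text I/O is
locale-independent with dot decimals; positions are written to 0.001 mm
and energies to 0.1 MeV (their declared storage precisions), other
numerics with shortest-round-trip precision, so write-then-read is the
identity. `#` comment lines carry provenance (session id, tool version)
without touching the dialect.

DICOM RT Ion Plans are read and written natively (explicit VR little
endian): one beam per field, one control-point pair per layer, spot
positions from the scan-spot position map and absolute MU from meterset
weight × beam meterset / final cumulative meterset weight, so
tolerance checks are always in MU regardless of a plan's weight
convention. Positions in DICOM are 32-bit floats, which bounds the
round-trip error at ~1e-5 mm — far inside the 0.001 mm storage
precision. Zero final cumulative weight, non-modulated scan modes and
missing scan-spot attributes are format errors naming the beam.

## Numerical choices and degenerate inputs

* Layer decomposition on an empty layer is a domain error, not NaN.
* The centroid-removal identity is exact in floating point to ~1e-16
  per spot; tests assert 1e-12 and the residual-sum bound at 1e-9 mm.
* Baseline lookup interpolates linearly in energy (the 96-level grid is
  dense) and takes the nearest tabulated gantry angle on the circle
  (commissioning angle grids are coarse); an energy outside the
  tabulated span is a configuration error, not an extrapolation.
* Histograms use half-open bins with a closed last bin, so counts plus
  out-of-range values always total the input size.
* Trend SDs are sample SDs (n−1); pooled means are plain means over the
  pooled observations, which makes them exactly the count-weighted
  means of per-session means.
* Fleet simulation sizes used by the test-suite consistency checks
  (200 sessions of 10 × 30 spots for recovery; 10,000 layers of 10
  spots for the flag-rate check) were chosen to bound the Monte-Carlo
  error of every recovered SD near or below 2%, comfortably inside the
  10% acceptance band.

## Known limitations

* The dose surrogate is planar and depth-free; no CT, RBE or DVH.
* The MU alarm default is a placeholder; clinical use requires the
  site's own tolerance file.
* The simulator's Gaussian error model cannot reproduce machine drift,
  quantization or interlock behaviour.
* The gamma search lattice trades a small, documented resolution effect
  for exact oracle agreement; sub-lattice minima are not found.
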