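---
title: "Methods: synthetic membranes, contact analytics and activation kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic membranes, contact analytics and activation kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidgate)
```

# Scope

`lipidgate` implements the analysis layer of a two-armed study of
diacylglycerol (DAG) regulation of the TRPC3 cation channel: contact,
occupancy and density analytics over coarse-grained membrane trajectories
around a fixed tetrameric channel model, and kinetic analysis of
photocurrents recorded under repetitive photoswitching of a DAG analogue
("optical lipid clamp"). Because neither µs-scale Martini trajectories nor
patch-clamp recordings are practical inputs at desk scale, the package
carries a first-class synthetic-data module that generates both kinds of
input with the statistical structure the analysis assumes. Everything
downstream — contact counting, fingerprints, occupancy, density maps, model
fitting, group statistics — operates identically on imported data
(GRO coordinates, CSV traces).

# The synthetic membrane generator

## What it emulates

The generator reproduces the *design* of the reference CG simulations, not
their physics:

* An asymmetric bilayer of PC/PE/PS/cholesterol, ~24 × 24 × 12 nm with
  ~1300 lipids, with DAG placed only in the inner leaflet at 2% or 10% of
  inner-leaflet lipids (1% or 5% of all lipids with equal leaflets).
* A restraint phase: DAG is confined to the inner leaflet for the first
  5 µs, letting the other lipids equilibrate around the protein, then
  released to flip freely between leaflets (DAG needs no transporter); runs
  continue to 20 µs (or 40 µs for the DAG-poor systems).
* Species- and site-dependent accumulation at the L1 (voltage-sensor-like
  domain) and L2 (pore domain) coordination pockets of the fixed,
  four-fold-symmetric channel model.

Physics is replaced by a *site-and-dwell* stochastic model: lipids take 2D
Brownian steps within their leaflet under periodic X/Y boundaries; DAG
flips leaflets as a Poisson process (rate zero during the restraint);
a lipid entering a free pocket's capture radius binds with a species- and
site-specific probability and dwells for an exponential residence time at
the pocket center. This preserves exactly the observables the analysis
measures — enrichment, time-to-equilibrium, flip-flop, occupancy — while
running in seconds.

## What it does not emulate

No force field, thermostat, solvent, elastic network, protein flexibility,
realistic lipid shapes (one reference bead per lipid), cooperativity
between pockets, or absolute CG kinetics. Tests passing on this generator
therefore validate the *analysis operators and their statistical
assumptions*, not any claim about real bilayer physics.

## Timeline and time compression

Schedules are stated on the original µs axis (5 µs restraint, 20 µs total,
frames saved every 0.1 ns) and compressed by a single factor (default
1000×): frames are analysed every `0.1 ns × 1000 = 100 ns` of original
time, and the dynamics parameters (diffusion, flip rate, dwell times) are
effective rates per compressed step. All analysis parameters are stated on
the same original axis, so the 200-ns smoothing window spans 3 frames (its
centered window is rounded to an odd point count).

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| contact cutoff | 0.6 nm | the CG bead contact distance used throughout |
| box, lipids | 24×24×12 nm, 650/leaflet | reference system size (~1300 lipids) |
| area per lipid | 0.64 nm² | typical fluid-phase value; sets lattice spacing |
| restraint | 5 µs of 20 µs | reference protocol |
| frame interval | 100 ns (compressed) | 0.1 ns saved interval × 1000 |
| repeats | 5 | reference repeat count |
| DAG flip rate | 0.3 /µs | gives tens of flips per molecule after release; DAG-only |
| capture radius | 0.55 nm | pocket entrance scale, slightly below the contact cutoff |
| DAG dwell at L2 | 16 µs | calibrated, see below |
| other dwell | 250 ns (325 Chol) | short annular-exchange scale |
| capture prob | DAG 0.9/0.8, others 0.12 | DAG avidity at the pockets |
| G652A factor | 0.3 | multiplies L2 DAG capture *and* dwell; emulates the mutant's reduced tetramer occupancy |

The binding defaults were calibrated once, before the test suite existed,
so that the shipped 1%-total-DAG condition settles at a steady L2
occupancy of 2–3 DAG molecules per tetramer (the double-to-triple
lipidation of closed tetramers reported for the reference systems):
across six pilot seeds the chosen set gave 2.10 ± 0.33. They have not been
revisited since. The G652A mechanism is unknown, so the mutant is a single
free factor (< 1) on L2 DAG affinity, not a structural model.

## Leaflet bookkeeping

Flip detection on the analysis side assigns a lipid to a leaflet by its
reference-bead Z against the bilayer midplane, with a ±0.5 nm hysteresis
band (the previous assignment is kept inside the band) to suppress
single-frame flicker. The generator also records its internal ground-truth
leaflet state; the two agree in the tests.

## Rounding and placement

Per-leaflet species counts come from mole percentages by largest-remainder
rounding, which keeps leaflet totals exact (ties broken by species order).
Lipids are placed on a jittered square lattice (spacing `sqrt(APL)`)
excluding the protein footprint; a box that cannot hold the requested
count at the stated area per lipid is a sizing error, not a warning.

# Contact analytics: three distinct definitions

The three figures of merit use three deliberately different counting
units, each pinned to its analysis:

1. **Molecules near the protein** — a lipid molecule counts once if *any*
   of its beads is within the cutoff of *any* protein bead
   (minimum-image). Used for shell equilibration over time.
2. **Bead pairs at a site** — (site-residue bead, lipid bead) pairs within
   the cutoff, summed over the four subunits. The reference analysis
   selects beads near the site residues, so the bead-pair unit is the
   natural reading; a per-subunit breakdown is an option.
3. **Distinct DAG molecules at L2** — the tetramer's lipidation level.

The shipped site definitions are the eight L1 residues (W334, C350, L351,
L354, A390, I394, N560, M586) and nine L2 residues (E615, F618, K619,
F622, W623, N645, Y648, A649, G652), replicated over subunits 1–4.

Distances are minimum-image in X/Y always and in Z only when the box is
flagged periodic in Z (the synthetic membranes are not). A cutoff at or
above half the smallest periodic edge is rejected as ambiguous. Neighbor
search runs either as a vectorised all-pairs evaluation (< 1000 beads) or
a cell list with cell edge ≥ cutoff; both paths are under an
identical-results contract enforced by test against an independent
per-bead enumeration oracle.

Cross-repeat series are smoothed per repeat with a centered,
edge-truncated moving average (no phase lag; a constant series is
unchanged), then averaged; the SD band is across repeats and only defined
for ≥ 2 repeats. Fingerprint percentages pool all lipid species in the
denominator, accumulate raw per-frame pair counts (no windowing before
summation), and rows of residues with no contacts are flagged rather than
divided by zero.

Equilibration onset is the earliest time after which the sliding-window
mean stays within 5% of the final-window mean for the remainder; a series
that only satisfies this inside the last probe window returns the
none-marker `NA`.

# Density maps

Species-resolved voxel histograms at 0.1 nm default resolution, half-open
voxel intervals, positions wrapped into the primary box; optional
normalisation to number density (counts / voxel volume / frame). No
trajectory alignment is performed — the protein is positionally fixed in
both the reference systems (restrained backbone) and the generator — and
no Gaussian smearing is applied: the map is a raw histogram, a deliberate
simplification relative to viewer-interpolated maps. Output is plain-text
OpenDX, readable by standard molecular viewers.

# Activation kinetics

## The models

The first ("naive-state") activation is fitted with a power exponential
plus a linear component,

$$I(t) = I_0 + A\,(1 - e^{-(t-t_0)/\tau})^p + m\,(t-t_0),$$

and later ("sensitized-state") activations with the same form without the
linear term. The verbal model description leaves additivity of the linear
term and the Hodgkin–Huxley-style power form as choices; both follow the
subunit interpretation of the power (p close to 4 for naive wild-type
activation, smaller once sensitized). Tau-ON is *defined* as the fitted τ
(not a 10–90% rise time), and sensitization as the fold change
τ_first/τ_second; values above 1 mean faster second activation.

## The fitting machinery

Bounded robust nonlinear least squares: a soft-L1 loss
ρ(z) = 2(√(1+z) − 1) on squared scaled residuals, the scale set from
1.4826 × MAD of an ordinary pilot fit's residuals, minimised over
box-constrained parameters with a quasi-Newton bounded optimizer
(`optim(method = "L-BFGS-B")`, τ on the log scale for conditioning),
multi-started over a τ decade grid (10⁻²…10¹ s) crossed with
p ∈ {1, 2, 4, 8}, with a tight-tolerance polish from the incumbent. On
(near-)noiseless data — pilot residual scale below 10⁻⁸ of the data range
— the ordinary loss is used directly, which is what makes exact
parameter recovery possible. Default bounds: τ ∈ [10⁻³, 10²] s,
p ∈ [1, 12] (continuous), A ∈ [0, 10 × range], m ∈ [−10, 10] pA/pF/s.
Degenerate flat segments pin A at 0 with a warning; total
non-convergence returns a flagged fit, never an exception. Fits are
deterministic for fixed inputs.

Blue-light (deactivation) epochs are generated (mono-exponential decay)
but not fitted by default; model choice follows segment position (first
UV epoch → naive model, later → sensitized model) with an override.

## Ramp, fluorescence and statistics utilities

Net I–V curves are stimulated-minus-background sweeps on the −130…+80 mV
ramp; the reversal potential is the zero crossing nearest 0 mV by linear
interpolation between bracketing samples (none-marker when the current
never changes sign), and current densities are read at −90 and +70 mV.
F/F₀ divides by a cell-free background series (the reference method) or,
optionally, by the pre-stimulus mean. Group comparisons follow the
recording-analysis scheme: Shapiro–Wilk per group, then t-test (with
Levene's test informing the equal-variance choice) or ANOVA for > 2
groups when all groups look normal, otherwise Mann–Whitney
(Kruskal–Wallis for > 2); constant groups fall to the rank branch with a
note.

## Trace generator defaults

Naive activation: A = 50 pA/pF, τ = 2 s, p = 3.6, m = 1 pA/pF/s —
the wild-type-like first-activation shape. Sensitized overrides: τ/3,
p = 2, 1.2 × A. Noise SD 1 pA/pF (2% of A); deactivation τ 0.5 s;
sampling 200 Hz. The synthetic ramp sweep uses 0.2 pA/pF noise, a typical
residual after 2 kHz low-pass filtering. The fluorescence trace is a
low-pass-filtered (τ = 1 s), linearly scaled copy of the noiseless
current deviation, exactly 1 when the current sits at baseline.

# Problem sizes in the shipped tests and scripts

The test-suite and acceptance-script studies use reduced problem sizes
chosen as the smallest at which each statistic is well-behaved: full-size
membranes (650 lipids/leaflet, 20 µs, 5 repeats) for occupancy and
fingerprint shares; 200-lipid-per-leaflet, 12 µs single-repeat systems for
the 20-seed enrichment and wild-type/G652A pairing (at 2% inner DAG only
4 DAG molecules exist and the per-seed statistic degenerates, so the
10%-inner condition is used there); 100 noisy segments at 100 Hz for
parameter recovery; 50 replicates for the fold-change band.

# Known limitations

* One bead per lipid: bead-level and molecule-level counts differ only
  through the protein side; multi-bead lipid topologies are supported by
  the operators but not generated.
* Pockets capture from the inner leaflet only, and at most one lipid each.
* The mutant model is a scalar affinity factor; it cannot distinguish
  capture- from dwell-limited mechanisms.
* The equilibration criterion is a pragmatic plateau detector, not a
  statistical test.
* Scenario plotting is deliberately out of scope; results are tidy CSV /
  JSON / OpenDX files.
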