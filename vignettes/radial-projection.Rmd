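---
title: "Radial projection of pencil-beam dose grids: method and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial projection of pencil-beam dose grids: method and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radproj)
```

## The model

A scanned proton pencil beam hitting a scoring plane perpendicularly is
axially symmetric to good approximation, so the expected dose at a voxel
depends only on its radial distance $r$ from the beam axis. Monte-Carlo
scoring of such a plane on a Cartesian voxel grid wastes that symmetry: each
voxel's score is an independent noisy sample, and in the low-dose tail —
which a clinical beam model must capture down to $10^{-4}$ of the central
dose — single-voxel scores are useless at practical history counts.

Radial projection recovers the symmetry after the fact. With the beam
center on a voxel center, the offsets $(\Delta i, \Delta j)$ of every voxel
are integers, and voxels share a radius exactly when they share the integer
key $\Delta i^2 + \Delta j^2$. Grouping on this key is free of
floating-point tie-breaking: the group at key 2 ($r = \sqrt 2$) has exactly
the 4 members $(\pm1, \pm1)$; key 25 ($r = 5$) has 12 members. The mean of
a group's scores — the *point average* — is the representative score for
that radius, with statistical uncertainty reduced by about
$1/\sqrt{n}$ relative to a single voxel.

Multiplicities grow roughly linearly with radius (the count of lattice
points in an annulus approaches its area), but the dose falls much faster,
so beyond some radius even point averages are noisy. There a *threshold*
$T$ — a fraction of the peak point-average dose — defines:

* the **boundary** $R_0$: the first radius (ascending) whose normalized
  point average is $\le T$; and
* **interval bins** for $r \ge R_0$: consecutive radius points accumulate
  into a bin until the running sum of their normalized point averages
  reaches $T$, so bins widen as the dose falls.

Each bin is represented by the voxel-count-weighted mean score
$\bar S = \sum n_i x_i / \sum n_i$ and radius
$\bar R = \sum n_i r_i / \sum n_i$. Per-entry uncertainty is the relative
standard error of the member voxel scores,
$\mathrm{RSE} = 100\% \cdot \sqrt{\sum_i (x_i - \bar x)^2 / (n(n-1))} / \bar x$,
undefined for $n < 2$ or a zero mean.

## Conventions and design choices

Several points of the procedure admit more than one reasonable reading;
the package fixes them as follows.

* **Weighting of $\bar S$, $\bar R$.** Whether the interval sums run over
  voxels or over radius points is genuinely open. The default weights by
  voxel count ($i$ runs over voxels): it maximizes statistical efficiency
  (every voxel contributes equally) and makes conservation exact — the
  voxel-weighted dose sum of the profile equals the slice's total dose up
  to floating-point associativity, which the suite checks at $10^{-12}$
  relative. `weighting = "point"` gives the unweighted-over-points variant
  for sensitivity checks; it does not conserve dose.
* **Normalization.** Both the boundary search and the interval
  accumulation use the same $T$ on the profile normalized to its peak
  point average; stored doses remain raw.
* **Boundary semantics.** The first crossing wins, equality included, even
  if the profile rebounds above $T$ afterwards; points exactly at $R_0$
  belong to the interval region ($r \ge R_0$). An optional `persistence`
  parameter requires $k$ consecutive sub-threshold points before accepting
  the crossing, as a guard against noise-driven premature boundaries; the
  default $k = 1$ is the literal rule.
* **The final bin** may end with its running sum still below $T$; it is
  kept and flagged `partial` instead of dropped, so the profile never
  silently truncates the tail.
* **Beam center** defaults to the geometric center voxel of the plane.
* **Degenerate inputs.** An all-zero slice has no peak to normalize by:
  the boundary is `Inf` and the whole profile is a point region of zeros
  with undefined RSE. A threshold never reached likewise leaves the whole
  profile in the point region.
* **Anisotropic planes.** Exact integer grouping requires isotropic
  in-plane spacing; otherwise grouping errors out and a tolerance mode
  (physical $r^2$ quantized to 9 significant digits) is available.

## The synthetic beam

The generator emulates MC scoring output without transport physics. The
expected lateral dose is a double Gaussian,
$D(r) = A[(1-w)e^{-r^2/2\sigma_c^2} + w e^{-r^2/2\sigma_t^2}]$ — the
Gaussian core plus broad low-dose tail that measured spot profiles show.
Voxel scores are independent scaled Poisson draws with expected count
$cND(r)/A$, where $N$ is the emulated history count and $c$ a calibration
constant (expected peak count per history), so per-voxel relative noise
follows the $1/\sqrt{\text{counts}}$ law that real MC voxel scoring obeys.
Where the expected count exceeds $2^{30}$ a Gaussian of matching mean and
variance (truncated at zero) replaces the Poisson draw. All randomness is
seeded per call and the global RNG stream is left untouched.

The default fixture is a 201×201 plane at 1 mm spacing with
$\sigma_c = 6$ mm, $\sigma_t = 25$ mm, $w = 0.05$, $A = 1$, scored with
$N = 2\times10^7$ emulated histories at $c = 5\times10^{-4}$ (so $10^4$
expected peak counts). The tail parameters were chosen once so that the
profile spans the $10^{-4}$ dynamic range a clinical beam model needs
within the plane's 100 mm half-width; they are a plausible stand-in, not a
calibration to any particular machine. Optional elliptical asymmetry
(`make_elliptical`, axis ratio 1.05–1.15 as beams show at the isocenter,
average 1.09) scales the two axis sigmas by $\sqrt\rho$ and $1/\sqrt\rho$,
preserving iso-dose contour areas.

What the generator does *not* emulate: correlated scoring noise
(neighboring-voxel correlations from secondary particles), depth evolution
(each slice is independent; no Bragg peak), beam-center uncertainty, and
non-Gaussian halo components. Tests passing on this fixture therefore
demonstrate the projection arithmetic and its statistical behavior under
ideal counting noise, not agreement with any real nozzle.

## Uncertainty comparison

The conventional profile reads single-voxel scores along one ray out from
the center, so within one slice its RSE is undefined — there is one voxel
per radius, nothing to average. `compare_methods()` therefore estimates
the conventional profile's uncertainty as the across-replicate relative
standard deviation of the single-voxel score at each ray radius — the
single score *is* the conventional estimator, so its relative SD is its
uncertainty — while the RP profile's uncertainty is the within-slice RSE
averaged over region entries and then over replicates. Region means are
unweighted over radius points; undefined entries (zero replicate mean in
the deep tail) are excluded and counted. The default comparison region is
the tail $[R_0, r_\text{edge}]$ with $R_0$ computed from the noise-free
beam at the same threshold, so both methods are judged on identical ground.

At desk scale the absolute RSE values of a real nozzle simulation are not
reproducible; what is reproducible is the structural claim, and it is
checked as a stochastic property: with $10^4$ peak counts and 50
replicates, the RP tail RSE at one tenth of the histories stays below the
conventional tail RSE at the full count (by a wide margin — the measured
equal-quality reduction factor on the fixture is several hundred, since
tail bins pool thousands of voxels).

## Field synthesis

`radial_to_function()` interpolates a profile linearly in dose through the
point region and linearly in log-dose through the tail (falling back to
linear across zero-dose entries), returning zero beyond the last radius.
`square_field_central_dose()` superposes identical spots on a square grid
centered on the field — spot positions at integer multiples of the spacing,
included when the spot center lies within the field boundary (inclusive),
the simplest defensible convention — and evaluates the summed dose at the
exact field center with no detector-volume averaging.
`output_factor_curve()` normalizes central doses to a reference field
(default 100 mm side). The broad tail is dosimetrically consequential
here: a tailed profile shows markedly more output-factor growth from 2 cm
to 20 cm fields than a pure-core profile, which the suite checks.

## Numerical notes and problem sizes

Exact grouping keys are integers (no tolerance needed); per-group means
and centered sums of squares are computed by a vectorized two-pass scheme,
so Eq.-3 RSEs are free of catastrophic cancellation and interval-bin RSEs
pool member groups exactly. The double-Gaussian fit
(`fit_double_gaussian`) uses Levenberg–Marquardt with starts derived from
the peak and half-maximum radius; with $10^6$ peak counts it recovers
$\sigma_c$ of the fixture within 2%, which the suite asserts.

The test suite runs the statistical properties at sizes chosen for a
desktop: 200-replicate $1/\sqrt n$-scaling checks on 21×21 planes,
50-replicate method comparisons and the parameter-recovery fit on the full
201×201 fixture; the whole suite completes in a few seconds. The
acceptance script's doubling search (11 comparisons × 50 replicates ×
40401-voxel slices) completes in well under a minute.

## Known limitations

* The method presumes axial symmetry; applied to an elliptical beam it
  averages over the azimuth and biases the profile — the generator can
  produce such beams precisely so that this bias can be studied, but the
  projection itself does not correct it.
* Projection is strictly per-plane (2D); no spherical/3D grouping.
* No resampling of the profile onto a uniform radius grid; consumers get
  the exact lattice radii and bin representatives.
* The interval-accumulation rule ties bin widths to the *threshold* alone;
  at very low history counts the normalized point averages entering the
  running sum are themselves noisy, and bin edges become stochastic.
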