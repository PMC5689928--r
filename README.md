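# radproj

Radial-projection post-processing of Monte-Carlo-generated pencil-beam dose
grids.

## The problem

Commissioning a proton spot-scanning treatment planning system requires
lateral dose profiles of the pencil beam measured down to ~0.01% of the
central dose. Monte Carlo (MC) simulation can generate them, but the
stochastic voxel scores in the low-dose tail are dominated by counting noise
unless enormous history counts are run. A scanned pencil beam, however, is
axially symmetric: on a lateral scoring plane every voxel at the same radial
distance *r* from the beam axis is an independent sample of the same
expected dose.

The **radial projection (RP)** method exploits this. Each voxel at offset
(Δi, Δj) from the beam-center voxel is assigned the exact squared radial key
Δi² + Δj²; all voxels sharing a key share a radius, and their mean — the
**point average** — replaces any individual score. On a unit lattice the
multiplicity *n(r)* is the number of representations of Δi² + Δj² as a sum
of two squares (4 voxels at r = √2, 12 at r = 5, growing roughly linearly
with r), so the statistical uncertainty of the representative score falls by
about 1/√n(r).

In the far tail even point averages stay noisy, so a **threshold** T (a
fraction of the peak point-average dose) defines a **boundary**
R₀ — the first radius whose normalized point average ≤ T — beyond which
consecutive radii are merged into variable-width **interval bins**: a bin
closes when the running sum of normalized point averages reaches T, and is
represented by the voxel-count-weighted mean score S̄ = Σnᵢxᵢ/Σnᵢ and radius
R̄ = Σnᵢrᵢ/Σnᵢ. Statistical quality of any profile entry is quantified by
the relative standard error of its member scores,

    RSE = 100% · sqrt( Σ(xᵢ − x̄)² / (n(n−1)) ) / x̄ .

The package implements the full pipeline plus a seeded synthetic
double-Gaussian beam (Poisson counting noise, optional elliptical
asymmetry) so everything is testable without any external dataset, and a
square-field output-factor synthesizer that superposes spot profiles on a
scan grid.

## Worked example

```r
library(radproj)

model <- default_beam_model()            # core 6 mm, tail 25 mm, weight 0.05
slice <- simulate_slice(model, default_sim_config(seed = 42))
rp    <- radial_profile(slice, threshold = 0.01)
rp
#> <radial_profile> threshold 0.01 of peak 1.005
#>   boundary R0 = 44.41 mm; 612 point radii (r < R0), 282 interval bins (r >= R0)
#>   (final bin is partial: running sum below threshold at profile end)
#>   voxel-weighted interval averages; voxel-weighted dose total 411.212
```

The 201×201 plane's 40401 voxels collapse to 612 exact radii below the 1%
boundary at 44.4 mm and 282 interval bins beyond it; the voxel-weighted
dose total equals the slice total exactly. Per-entry uncertainty:

```r
head(rse_curve(rp), 4)
#>   radius_mm n rse_percent region
#> 1  0.000000 1          NA  point
#> 2  1.000000 4   0.4770343  point
#> 3  1.414214 4   0.1752289  point
#> 4  2.000000 4   0.5535000  point
```

The origin has a single voxel (RSE undefined); at radius 1 mm four voxels
already cut the ~1% single-voxel noise in half. Comparing methods — the RP
profile from *ten times fewer* emulated histories against the conventional
single-ray read-out at full histories:

```r
compare_methods(model, n_conventional = 2e7, n_rp = 2e6,
                replicates = 50, seed = 42)
#> <rp_comparison> region 44.91..100 mm, threshold 0.01, 50 replicates
#>   RP:           mean RSE 8.540% at N = 2e+06 histories
#>   conventional: mean RSE 63.966% at N = 2e+07 histories (0 zero-mean radii excluded)
#>   uncertainty reduction factor (conventional / RP): 7.490
```

Even at a tenth of the histories the RP tail is ~7× less noisy than the
conventional ray at the full count.

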