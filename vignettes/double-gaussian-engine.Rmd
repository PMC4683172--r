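---
title: "The double-Gaussian pencil-beam dose model and its implementation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The double-Gaussian pencil-beam dose model and its implementation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halodose)
```

## The dose model

A scanned proton field is a set of pencil beams (PBs), each defined by an
energy, a lateral spot position and a weight.  A single Gaussian describes
the lateral profile of a PB well in the high-dose core but misses the
low-dose *halo* of particles travelling at large angles — nuclear secondary
particles, nozzle scattering, large-angle Rutherford scattering.  Although
the halo dose is locally small, the halos of many spots overlap: the central
dose of a square field grows measurably with field size, which a
single-Gaussian model cannot reproduce.

This package implements a double-Gaussian beam model.  The dose at a point
is a sum over computational pencil beams (CPBs, the sub-spot elements of
the primary dose) and halo pencil beams (HPBs, one per physical spot):

$$D(x,y,z)=\sum_{i\in\mathrm{CPB}}(1-u)\,N_i\,I_{\mathrm{IDD}}(E,z_{WE})\,
G(x-x_i,y-y_i,\sigma_{\mathrm{CPB}})
\;+\;\sum_{j\in\mathrm{HPB}}u\,N_j\,I_{\mathrm{IDD}}(E,z_{WE})\,
G(x-x_j,y-y_j,\sigma_{\mathrm{HPB}})$$

where $I_{\mathrm{IDD}}$ is the integral depth dose at water-equivalent
depth $z_{WE}$, $u(E,z_{WE})\in[0,1]$ is the *halo fraction* — the share of
the integral dose carried by the halo — and $G$ is a unit-integral 2D
Gaussian.  The halo kernel width is the quadrature sum

$$\sigma_{\mathrm{HPB}}^2=\sigma_{\mathrm{PB}}^2+\sigma_{\mathrm{LA}}^2,
\qquad
\sigma_{\mathrm{PB}}^2=\sigma_{\mathrm{air}}^2+\sigma_{\mathrm{CPB}}^2,$$

with $\sigma_{\mathrm{air}}$ the in-air width at the patient surface,
$\sigma_{\mathrm{CPB}}$ the multiple-Coulomb-scattering growth and
$\sigma_{\mathrm{LA}}$ the large-angle component supplied, like $u$, by a
halo parameterization.

## The two halo parameterizations

**Soukup model.**  Analytic fits to Monte-Carlo simulations of nuclear
interaction products in water give $u$ and $\sigma_{\mathrm{LA}}$ as closed
forms in the Bragg-peak depth $R_0$ and $z_{WE}$
([`soukup_halo_fraction()`], [`soukup_sigma_la()`]).  Where the
halo-fraction expression goes negative it is clamped to zero; past the
Bragg peak both quantities hold their peak-depth value (the hold is applied
to both, though the original statement makes it explicit only for $u$ —
holding the width as well is the only choice that keeps the model defined
up to the 105% evaluation cap).  The expressions contain a pole at
$z_{WE}=R_0+3\,$mm; the past-peak hold substitutes
$z \leftarrow \min(z_{WE},R_0)$, so the pole is never reached.

**Direct model.**  Sums of two Gaussians are fitted to radial dose
profiles at many depths ([`fit_double_gaussian()`]); $\sigma_{\mathrm{LA}}$
follows by rearranging the quadrature rule, and penalized cubic splines
smooth the resulting depth curves ([`build_direct_model()`]).  Past 102% of
the Bragg-peak depth the two-charged-Gaussian picture collapses (the second
Gaussian starts chasing the broad "aura" of neutral secondaries: fitted
$u$ drops sharply, then tends to one while $\sigma_{\mathrm{LA}}$ blows
up), so fits beyond the 102% hold are excluded and the curves frozen at
their value there.

Because the direct model attributes part of the *surface* dose to the halo,
the primary entry width must shrink so that the combined profile keeps the
measured in-air width: a single factor of 0.97 on the entry width
([`entry_width_factor()`]) is applied when distributing CPB weights — never
to the scattering growth.  The Soukup model has essentially no surface halo
and uses no correction.

### Fitting details

Per-depth fits minimize ring-area-weighted least squares: the squared
residual of bin $[r_i, r_{i+1})$ is weighted by $\pi(r_{i+1}^2-r_i^2)$, so
the sparse large-radius dose — where the halo parameters are actually
determined — is not drowned out by the core.  The optimizer is bounded
Levenberg–Marquardt (`minpack.lm`), with $u\in[0,1]$,
widths in $[0.1, 200]$ mm, and the ordering
$\sigma_{\mathrm{HPB}}\ge\sigma_{\mathrm{PB}}$ built into the
parameterization ($\sigma_{\mathrm{HPB}}=\sigma_{\mathrm{PB}}+\Delta$,
$\Delta\ge 0$), which also removes the label-switching ambiguity.
Initialization: $\sigma_{\mathrm{PB}}$ from a single-Gaussian fit,
$\sigma_{\mathrm{HPB}}=3\sigma_{\mathrm{PB}}$, $u=0.1$.  The two-Gaussian
likelihood has a degenerate second mode in which the roles of the
components flip ($u\to 0.9$); when a fit lands there, it is refit from a
low-$u$ start and the physical branch is kept whenever it fits comparably
well — a concrete form of the usual preference for a limited halo fraction.

The smoothing stage uses penalized cubic regression splines (`mgcv`, REML)
on a $\sqrt{z/R_0}$ abscissa — halo depth curves rise steeply near the
surface, and the square-root stretch resolves that curvature — with
inverse-variance weights from the per-depth fit covariances and one
robustness reweighting pass (running-MAD scale, bisquare weights) to guard
against occasional near-degenerate fits whose asymptotic errors are
optimistic.  Plain generalized cross-validation on the raw depth axis was
tried first and both oversmoothed the surface region and chased outliers;
REML with the transformed abscissa is stabler at these sample sizes.

### Primary width growth and its calibration

$\sigma_{\mathrm{CPB}}(z_{WE})$ grows from zero at the surface by
Fermi–Eyges integration of a Highland-type scattering power
$T=(E_S/pv)^2/X_0$ along the water-equivalent path, with the
proton's $pv$ from the residual Bragg–Kleeman range and $X_0$ the
radiation length of water; an empirical correction $\delta\,z_{WE}/R_0$ is
added so that $\delta$ has units of mm and vanishes at the surface.  $E_S$
(MeV) and $\delta$ (mm) are the model's only free parameters; the
single-Gaussian reference values are 14.1 MeV and 0.21 mm.  With a
double-Gaussian model both must be recalibrated against the *primary*
contribution alone: the halo predicted by the chosen parameterization is
subtracted from each radial profile, the remainder fitted with a single
Gaussian ([`extract_sigma_pb_soukup()`]; the subtraction iterates because
the halo kernel depends on $\sigma_{\mathrm{PB}}$, but since
$\sigma_{\mathrm{LA}}$ is generally at least twice $\sigma_{\mathrm{PB}}$
it converges essentially after one pass), and
[`calibrate_scattering()`] fits $E_S$ and $\delta$ jointly over all
energies and depths.  Residuals are formed in total-width space
($\sqrt{\sigma_{\mathrm{air}}^2+\sigma_{\mathrm{MCS}}^2}$ against the
observed $\sigma_{\mathrm{PB}}$) rather than by subtracting
$\sigma_{\mathrm{air}}$ from the noisy data in quadrature, which would
amplify measurement noise where the scattering component is small.  The
$E_S$/$\delta$ split is poorly identified from a couple of energies alone;
a calibration should span the machine's energy ladder.

## The engine

The computational cost of a pencil-beam algorithm is dominated by the
*kernel superposition* (KS): spreading each element's integral dose over
its depth plane with its Gaussian kernel, at a cost proportional to
$(\sigma/\mathrm{spacing})^2$ per element.  A halo two to three times wider
than the primary would therefore cost four to nine times the primary KS if
computed the same way.  The engine avoids that with two reductions:

* **No sub-spot splitting for the halo.**  One HPB per physical spot
  (weight equal to the spot weight), versus roughly nine CPBs per spot at
  the default 3 mm spot / 1 mm CPB spacing.
* **A coarser halo grid.**  The halo is deposited, spread and stored on a
  separate beam's-eye-view (BEV) grid at the spot spacing, three times
  coarser than the primary BEV grid, cutting the KS cost by another factor
  of nine.

With halo kernels about three times the primary kernels, the two factors
put the halo KS near one ninth of the primary's; the package counts
element-times-voxel operations per pass ([`workload_report()`]) and the
suite asserts the constructed three-to-one case stays below 12%.

Per energy layer the engine: looks up $R_0$, $\sigma_{\mathrm{air}}$ and
the IDD from the beamline table; splits spot weights onto the fine lattice
with the (entry-corrected) in-air width, cell-integrated and renormalized;
raytraces WEPL along each fine-lattice column (cumulative
stopping-power-weighted path, trilinear sampling); per global z-plane
computes $u$, $\sigma_{\mathrm{LA}}^2$ (bilinear table lookup — the
*squared* width is what is stored and interpolated), $\sigma_{\mathrm{CPB}}$
and the IDD at the plane's WEPL, accumulating $(1-u)\,N\,I_{\mathrm{IDD}}$
on the fine grid and $u\,N\,I_{\mathrm{IDD}}$ on the coarse grid; runs the
two KS passes sequentially; and resamples both BEV grids to the global
frame.  Planes with $z_{WE}$ beyond $1.05\,R_0$ are inactive — the largest
WEPL the model evaluates.

Numerical choices worth knowing:

* **Kernels** are separable, cell-integrated, truncated at
  `truncation` (default 3.5) sigmas per axis and renormalized to unit
  mass, so plane sums are conserved to machine precision; the support
  never drops below one cell per side (a sub-cell sigma still leaks a few
  percent into the neighbour cells).
* **Depth bookkeeping**: the element "integral dose" at a plane is
  $N\,I_{\mathrm{IDD}}(z_{WE})$ evaluated at the plane's WEPL — the direct
  reading of the dose model; the BEV depth step equals the global grid
  z-spacing.
* **Resampling**: the fine BEV grid is resampled linearly (its nodes
  normally coincide with global voxel centres, making the transfer exact);
  the coarse halo grid uses separable Catmull–Rom cubic interpolation,
  because with linear interpolation the 3 mm halo grid alone contributed
  about 0.17% of the maximum dose in oracle comparisons — cubic resampling
  is what keeps the coarsened halo from costing accuracy.
* **Geometry**: normally incident parallel fields only (direction
  `c(0, 0, 1)`); scanning with a large effective source-axis distance is
  well approximated as parallel, and oblique incidence is out of scope.
  HPB positions are snapped to the nearest coarse node (exact for
  lattice-aligned plans, which all plan constructors produce).
* **Heterogeneity**: $\sigma_{\mathrm{CPB}}$ is grown in WEPL; there is no
  lateral heterogeneity correction within a kernel — the same
  approximation class as classical pencil-beam algorithms.
* With `model = "single"` the halo pass is skipped entirely; running the
  double-Gaussian engine with $u\equiv 0$ tables reproduces it bit for bit
  (the suite asserts identity).

## The synthetic ground truth

Everything a commissioning would take from Monte-Carlo simulation or
measurement is generated in code, so the pipeline is testable end to end:

* [`analytic_idd()`] — a Bragg-curve stand-in: rising plateau, Gaussian
  peak at exactly $R_0$ with width $0.022\,R_0$ (range straggling of about
  1.2% of range plus a typical machine momentum spread — the width that
  makes 20-layer spread-out Bragg peaks flat at conventional layer
  spacings), hard zero beyond $1.05\,R_0$.
* [`make_ground_truth_beam()`] — smooth $u$, $\sigma_{\mathrm{PB}}$,
  $\sigma_{\mathrm{LA}}$ depth curves with known values; defaults rise
  from $u=0.05$ at the surface to $0.25$ at the peak and keep
  $\sigma_{\mathrm{HPB}}/\sigma_{\mathrm{PB}}$ between roughly 1.9 and 2.6,
  the separation regime reported for real beam lines.  The profile at
  every depth is *exactly* a sum of two Gaussians.
* [`radial_profile_from_truth()`] — closed-form annulus averages (0.5 mm
  bins to 100 mm by default) with optional multiplicative Gaussian noise
  per bin (default 2%, seeded), emulating Monte-Carlo statistical error.
* [`make_phantom()`] — water tanks and slab phantoms;
  [`make_synthetic_beamline()`] — energy ladders with the analytic IDDs and
  a smooth in-air width model (wider spots at low energy).

What this synthetic world deliberately does **not** contain: the
non-Gaussian aura of neutral secondaries, nozzle-specific beam shapes,
measurement systematics, patient anatomy.  Passing the recovery tests
therefore shows the pipeline is *self-consistent* (it inverts its own
forward model exactly in the noiseless limit, and stably under
Monte-Carlo-like noise); it does not certify accuracy against a particular
physical beam line, which requires that beam line's reference data.

## Validation machinery

[`gamma_index()`] implements the global 3D gamma test: for each reference
voxel above a dose threshold (default 10% of the normalization dose), the
minimum over a search sphere of $\sqrt{(\Delta D/\delta D)^2+
(\Delta r/\delta r)^2}$, with $\Delta D$ relative to the reference maximum
or a prescription dose.  The evaluated dose is upsampled threefold by
trilinear interpolation to bound discretization of the distance term; the
search radius is $3\,\delta r$; offsets are visited in order of increasing
distance with per-voxel early termination.  The search refinement and
radius are conventional choices.  Gamma maps, passing rates,
dose-difference maps and radial profile extraction
([`radial_profile_of_dose()`]) cover the standard comparison workflow.

## Test problem sizes

The suite runs entirely on synthetic data: oracle equivalence on a
40×40×60 mm water grid with five spots against untruncated brute-force
summation (agreement within 0.1% of the maximum dose); parameter recovery
at $R_0 \in \{70, 131, 220\}$ mm with profiles every 1% of range
(noiseless within 1% relative RMS, 2% noise with a fixed seed within 5%);
and a 20-layer cubic-target plan on a 50 mm cube at 1 mm resolution with a
central-axis plateau flat to better than 5%.  These sizes keep the whole
suite in the minutes range on one core while exercising every code path at
realistic parameter values.

## Known limitations

* Normally incident fields only; no divergence, range shifters or
  apertures.
* No CT import or HU-to-stopping-power calibration; phantoms are synthetic.
* The halo tables are two-dimensional in $(R_0, z_{WE})$; any lateral or
  nozzle-configuration dependence of the halo is out of scope.
* The aura (neutral secondaries) is ignored by construction, consistently
  in the model, the fits and the ground truth.
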