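---
title: "Methods: voxel-wise BED for multi-isocenter radiosurgery plans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-wise BED for multi-isocenter radiosurgery plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bed3d)
```

## Scope and model

`bed3d` reconstructs 3D physical dose and biologically effective dose
(BED) for single-session, multi-isocenter Gamma Knife Model B/C plans
from shot parameters alone. The chain has three stages, each an
explicit model with checkable contracts:

1. **Profile model.** Measured single-shot falloff curves along the
   three frame axes are fitted with Gaussian sums
   $F(t)=\sum_i u_i e^{-((t-v_i)/w_i)^2}$ (the parameterisation used
   by standard curve-fitting tools; note $w$ is not a standard
   deviation — a single term has FWHM $2w\sqrt{\ln 2}$). The three
   axis fits are collapsed into one radial profile $F_L$ over the
   ellipsoid-expansion coefficient $L$: at each iso-dose level the
   per-axis half-widths $a,b,c$ are read off the fitted curves and the
   level is assigned the radial coordinate $L=(|a||b||c|)^{1/3}$, the
   radius of the sphere with the volume of the iso-dose ellipsoid.
2. **Dose engine.** A point at offset $\Delta$ from an isocenter maps
   to $L=(F_xF_yF_z)^{1/3}\sqrt{\sum_{\rm ax}\Delta_{\rm ax}^2/F_{\rm
   ax}^2}$, and the shot dose is $d_i=\dot d_i\,\delta t_i\,F_L(L)$.
   The printed form of this mapping in the source literature is
   ambiguous about the square root over the bracketed sum; dimensional
   analysis against the ellipsoid semiaxis relations forces the square
   root used here (without it, $L$ would carry units of mm²). Plan
   dose is the voxelwise sum over shots.
3. **BED engine.** Under the linear-quadratic model with
   bi-exponential repair, BED $=D_T+\frac{1}{\alpha/\beta}
   \frac{\Phi(\Xi,\mu_1)+c\,\Phi(\Xi,\mu_2)}{1+c}\sum_i d_i^2$, with
   $\Phi$ the generalised Lea–Catcheside interaction factor of the
   exposure sequence $\Xi$ (constant dose rate during each beam-on
   interval, zero during gaps).

Key modelling assumptions: dose falloff is separable into a purely
radial function of $L$ (exact for ellipsoidal iso-dose surfaces, an
approximation for real beam asymmetries); no tissue heterogeneity or
skull-attenuation corrections; dose is point-sampled at voxel centres,
not volume-averaged, matching 1 mm planning-matrix practice; shots are
delivered strictly in plan order with known gaps.

## The interaction factor as a quadratic form

$\Phi$ regroups exactly into voxel-independent timing weights: self
terms $A_j=\frac{2}{\mu}\,\frac{\delta t_j-(1-e^{-\mu\delta
t_j})/\mu}{\delta t_j^2}$ and pair terms, rewritten for numerical
stability as
$$B_{ij}=\frac{2\,e^{-\mu g_{ij}}\,\mathrm{expm1}(-\mu\delta t_i)\,
\mathrm{expm1}(-\mu\delta t_j)}{\mu^2\,\delta t_i\,\delta t_j},$$
where $g_{ij}$ is the idle time between the end of shot $i$ and the
start of shot $j$. This form is algebraically identical to the
textbook grouping
$-e^{-\mu(t_j-t_i)}(e^{\mu\delta t_i}-1)(e^{-\mu\delta t_j}-1)$ but
keeps every exponent non-positive, so it cannot overflow for fast
repair and long sessions. Because $A$ and $B$ do not depend on the
voxel, whole-grid BED evaluation is a set of array quadratic forms
over the sparse per-shot fields — $O(VN^2)$ multiply-adds with no
per-voxel exponentials — and is tested to agree with the voxelwise
formula to 1e-9 Gy.

Two properties deserve emphasis:

* $\Phi$ is normalised by $\sum_k d_k^2$, not $(\sum_k d_k)^2$. For a
  single shot $\Phi\in(0,1]$, but for several interacting shots the
  factor can legitimately exceed 1, up to $(\sum d)^2/\sum d^2$ in the
  acute zero-gap limit — which is precisely what restores the textbook
  acute BED $D+D^2/(\alpha/\beta)$ when a dose is split into
  coincident instantaneous shots. The package enforces this corrected
  bound, not $\Phi\le 1$.
* An independent oracle, `phi_numeric_oracle()`, evaluates the
  defining double integral by composite Simpson quadrature over the
  piecewise-constant dose-rate function, with step
  $\min(\delta t_{\min}/200,\;0.04/\mu)$. The second cap keeps the
  quadrature error itself below the 1e-6 agreement bound at fast
  repair rates; the inner integral is accumulated on the same lattice
  through a recursive filter so the oracle stays $O(\text{nodes})$.
  The oracle never uses the closed-form weights.

## Tunable parameters

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| `grid_spec()` size / spacing | voxels / mm | 200 / 1 | full Leksell frame at planning resolution; covers elongated organs at risk (150 mm tracts) |
| `max_terms` (profile fit) | – | 4 | smallest-N-first selection; 4 terms suffice for measured-style falloffs |
| `rmse_tol` (profile fit) | fraction of max dose | 0.005 | half a percent, at the level of film-dosimetry noise |
| iso-dose level grid (radial collapse) | fraction | 0.95…0.05 by 0.05 | uniform coverage of the falloff; extrapolated crossings beyond the measured offset range are rejected |
| `l_max` | mm | first radius with fitted $F_L<0.001$ | Gaussian sums may re-rise outside the data; truncation plus clamping to [0, 1] makes evaluation safe and compactly supported |
| `alpha_beta`, `mu_fast`, `mu_slow`, `partition_c` | Gy, 1/min, – | none | tissue- and literature-specific; a labelled example config ships in `extdata` (α/β 2.47 Gy, repair half-times 11.4 / 129.6 min, c 0.98). Rates may be entered as half-times, μ = ln 2 / t½ |
| `bin_width` (DVH) | Gy | 0.5 | planning convention; cumulative curves use at-or-above |

Time is minutes everywhere; relative dose is a fraction in [0, 1]
internally, with percent appearing only at I/O boundaries — one
convention avoids factor-100 bugs.

## Numerical choices

* **Fit initialisation is deterministic**: amplitude from the peak
  sample, widths from a moment estimate, plus a small fixed set of
  starting patterns per term count (width-spread stack,
  mirrored-centre pair, wide-positive/narrow-negative). No random
  restarts, so identical inputs give byte-identical serialized models.
  The mirrored and negative-amplitude patterns exist because
  flat-topped profiles trap a single-start Levenberg–Marquardt fit in
  the one-Gaussian local minimum.
* **Profile centre** is the midpoint of the half-maximum crossings,
  not the argmax: for flat-topped profiles the argmax is
  ill-conditioned (any point on the plateau maximises), while the
  half-max midpoint is the standard, stable beam-profile centre.
  Half-widths at every level are measured from this centre, and FWHM
  crossings are located by outward scan plus bisection to 1e-6 mm,
  taking the *outermost* crossing on each side.
* **Signed-L cloud, one-sided evaluation**: both falloff sides enter
  the radial fit (left half-widths with negative sign); the spatial
  mapping only ever produces $L\ge 0$, so any residual left/right
  asymmetry is averaged by the fit.
* **Degenerate inputs** error loudly: all-zero profiles, too few
  samples for the term budget (3 samples per term), axes whose
  iso-dose level ranges do not overlap, zero beam-on times (the
  interaction factor divides by $\delta t$; acute shots are modelled
  by short durations, whose limit is exact), all-zero dose vectors in
  $\Phi$ (voxels with no dose short-circuit to BED 0 instead).
* **Voxel convention**: voxel $(i,j,k)$ (1-based) is centred at
  $(i,j,k)\times$spacing mm, so the frame centre (100, 100, 100)
  coincides with a voxel centre and a centred shot's sampled peak is
  its true peak. Per-shot fields are stored as bounding boxes of the
  $l_{\max}$ ellipsoid and reconstruct exactly.
* **Iso-surfaces** use marching tetrahedra (six tetrahedra per cell
  sharing the cell diagonal) with linear edge interpolation; triangles
  are oriented outward by the local field gradient, so the enclosed
  volume follows from the divergence theorem and is cross-checked
  against voxel counting.

## What the synthetic generators emulate — and what they do not

`sim_profile_tables()` emulates TMR10- or film-style falloff tables
as flattened-top Gaussians with seeded measurement noise and a pinned
peak sample; the flat shoulder deliberately breaks the single-Gaussian
assumption so multi-term fitting is genuinely exercised, and the
generator records its exact true FWHM for recovery tests. The default
FWHM triples (4 → 6/6/4.8 mm, 8 → 11/11/9 mm, 14 → 18/18/15.5 mm,
18 → 24/24/20 mm, z narrowest) are fixture conventions near nominal
collimator sizes, not measured machine data. `sim_plan()` draws shots
uniformly inside a target box; `ellipsoid_mask()` and `tract_mask()`
voxelize analytic solids (the tract is a flat-ended tube around a
~165 mm arc). All generators are pure functions of their arguments
and seed.

Consequently, passing tests demonstrate internal consistency and
correct mathematics under ellipsoidal-falloff conditions; they do not
validate against measured machine profiles, real plan exports, or
profiles with plug/blocking asymmetries. Real z-profiles are also
mildly asymmetric, which the symmetric $L$ collapse averages away by
construction.

## Design decisions on open points

* The conformity and gradient indices are named but not defined in the
  source literature for this method; the package adopts the Paddick
  CI, $\mathrm{TV{:}PIV}^2/(\mathrm{TV}\cdot\mathrm{PIV})$, and the
  Paddick–Leksell GI, $V_{p/2}/V_p$, applied identically to dose and
  BED grids (any prescription level, in Gy or Gy$_{\alpha/\beta}$, is
  accepted).
* $F_L$ is treated as a fraction, not a percent, inside the dose
  equation; the literature mixes both notations.
* Start times generalise the adjacent-shot relation
  $t_{j}-t_i=\delta t_i+\delta t_{\rm gap}$ by accumulation:
  $t_{k+1}=t_k+\delta t_k+g_k$.
* The GI of a pure Gaussian field at a fixed *relative* prescription
  level is scale-invariant ($2^{3/2}$ at the 50% level regardless of
  width), so falloff-steepness comparisons in the tests vary the tail
  weight of the field rather than a width parameter.
* Shots whose truncation ellipsoid misses the grid contribute no dose
  but still occupy their slot in the exposure sequence — their beam-on
  time and gap elapse for every other shot's repair.

## Problem sizes and limitations

The test suite runs its grid comparisons on 20³–200³ matrices and its
quadrature/oracle comparisons over 50 randomized exposure sequences
(up to 6 shots, 0.5–30 min beam-on, 0–60 min gaps, μ from 0.01 to
5/min); geometry checks use 0.5 mm grids where voxel-count error at
1 mm would dominate the quantity under test. These sizes are the
package's chosen study conditions; all of them complete in seconds.

Out of scope by design: Perfexion/Icon/Esprit sector-composite shots
and beam-channel blocking; proprietary planning-file parsing; image
registration and rendering; fractionation across days;
tumour-control/complication probability models. The BED model itself
remains a hypothesis about dose-rate effects in radiosurgery — this
package makes it computable at voxel resolution, it does not validate
it clinically.
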