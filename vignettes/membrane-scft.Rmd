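---
title: "Molecular theory of membrane tubes and fission intermediates with memfis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular theory of membrane tubes and fission intermediates with memfis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memfis)
```

## The model

`memfis` solves a self-consistent field theory (SCFT) of lipid
self-assembly.  The lipid is represented as a Gaussian AB diblock
copolymer of $N$ segments: a hydrophobic tail block of fraction $f = 0.8$
(species A) and a hydrophilic head block of fraction $1 - f$ (species B).
Water is a short B-type homopolymer of $N_s = N/10$ segments.  Each
segment has statistical length $b$ and volume $1/\rho$; the natural lipid
end-to-end distance $R_0 = b\sqrt{N}$ is the unit of length.  A single
Flory–Huggins parameter, fixed at $\chi N = 30$, penalizes tail–water and
tail–head contacts and drives bilayer self-assembly.

Calculations are semi-grand canonical: the total segment density is fixed
(incompressibility, $\phi_A + \phi_B = 1$ pointwise) while lipid and
solvent are exchanged with a reservoir at exchange chemical potential
$\mu = \mu_l - \mu_s$ (in $k_BT$).  We fix the activity convention once:
the solvent activity is 1 and $e^{\mu}$ multiplies only the lipid weight;
any other choice shifts $\mu$ by a constant.  The grand potential
evaluated by `grand_free_energy()` is

$$\Omega \;=\; -e^{\mu} V Q_l[W] \;-\; \tfrac{1}{\alpha} V Q_s[W_B]
 \;+\; \int \! dV \left[\chi N \,\phi_A \phi_B - W_A \phi_A -
 W_B \phi_B\right],$$

with $\alpha = N_s/N$, $Q_l$, $Q_s$ the single-chain partition functions
in the total fields $W = w + \xi$ ($\xi$ is the pressure field enforcing
incompressibility), and densities assembled from the chain propagators
$q(\mathbf r, s)$ of the modified diffusion equation
$\partial_s q = \tfrac{1}{6}\nabla^2 q - W q$.  In the homogeneous limit
this reduces analytically to the Flory–Huggins grand potential

$$\omega(\phi_l) = \phi_l(\ln\phi_l - 1) +
\tfrac{\phi_s}{\alpha}(\ln\phi_s - 1) + \chi N f \phi_l (1 - f\phi_l)
- \mu\,\phi_l,$$

which the test suite uses as a closed-form oracle (`solve_homogeneous()`
inverts the stationarity condition by bisection).  Because the membrane
exchanges lipid with the reservoir, the planar bilayer tension obeys the
Gibbs adsorption relation $d\sigma/d\mu = -\Gamma < 0$: tension
*decreases* with $\mu$, passing through zero at a unique $\mu^\*$
(`find_tensionless_mu()`); with the defaults $\mu^\* \approx 11.66$.

## Numerics

* **Contour stepping.**  Symmetric operator splitting per contour step
  $ds$ (half field, full diffusion, half field), second order in $ds$ and
  unconditionally stable; $ds = 0.01$ by default, with the tail/head
  junction required to fall on a contour grid point.  The diffusion
  substep is spectral (exact) in fully periodic geometries and
  Crank–Nicolson in finite-difference directions; the axisymmetric
  geometry uses Strang ADI (half step in $z$, full step in $r$, half step
  in $z$), all tridiagonal solves in compiled code.  Discrete propagators
  are clamped at zero where ringing undershoots in regions of deep decay.
* **Grids.**  Cell-centered; the cylindrical axis is handled by the
  vanishing inner-cell flux, so $1/r$ factors stay regular and the
  flux-form Laplacian is exactly self-adjoint under the quadrature.
  Default resolution $dx = 0.1\,R_0$ for routine work and tests,
  $0.05\,R_0$ for production/acceptance runs; the $\chi N = 30$ interface
  (width $\approx 0.3\,R_0$) needs the finer spacing for
  sub-percent tensions.  Tube grids extend at least $6\,R_0$ beyond the
  outermost membrane, with the outer-cell fields pinned to bulk solvent
  (`boundary = "reservoir"`) to emulate the lipid reservoir; geometries
  where the membrane itself must reach the wall (e.g. planar bilayers in
  the stalk calculation) use plain no-flux walls instead.
* **Fixed-point iteration.**  `scft_converge()` iterates the
  self-consistency map with an exact pressure update (the
  incompressibility drive `kappa_incomp` acts only during iteration; the
  constraint holds exactly at the fixed point, residual
  $\lesssim 10^{-8}$ in practice).  Damped simple mixing
  ($\lambda = 0.05$, 100 iterations) is followed by Anderson acceleration
  (history 10–20, damping $\beta = 0.5$–$0.8$) with overshoot detection
  that flushes the history and falls back to simple mixing.  Densities
  entering the update targets are capped at 2 — physical fractions never
  exceed 1, so fixed points are unaffected, but the cap keeps the
  $e^{\mu}$-amplified transients of poor initial fields stable.
* **Field residual tolerance.** $10^{-6}$ (max norm) by default.  Tube
  states have a nearly soft radial drift mode whose last decades converge
  slowly; production tube solves use $10^{-5}$ with accelerator restarts,
  below which the measured radius is insensitive (well under 0.1%).

## Observables and calibration

Bilayer thickness is the distance between the two head-density maxima
flanking the tail core (sub-grid accurate by quadratic peak
interpolation), the same dark-band logic used on cryoEM micrographs; the
hydrophobic-core FWHM is exposed as a diagnostic.  Tube radii are
midplane radii, matching the fluorometry convention.  Tension is the
excess grand potential of the planar bilayer per unit area relative to
bulk solvent at the same $\mu$.

Two anchors map model units to physical units (`calibrate_units()`):

1. **Length**: the tensionless bilayer thickness (1.33 $R_0$ with the
   defaults) is assigned 5 nm, the standard fluid
   phosphatidylcholine value, giving $1\,R_0 \approx 3.75$ nm.
2. **Energy**: model free energies are $k_BT$ per
   $C = \rho R_0^3/N$ chains; $C$ is anchored through the POPC molecular
   volume (1.26 nm³), $C = (\mathrm{nm}/R_0)^3 / 1.26 \approx 42$.  POPC
   is the natural reference lipid for fluid-membrane experiments of this
   kind.  With $k_BT = 4.11\times10^{-21}$ J, tensions convert via
   1 $k_BT$/nm² = 4.11 Dyn/cm.

All R0-unit results are independent of both anchors; changing the
thickness target rescales nm outputs proportionally and nothing else.
The published tube radii this model family is compared against are
sensitive to the energy anchor (through which tension in Dyn/cm maps to
model tension): with the POPC-volume anchor the computed single-membrane
tube at 1 Dyn/cm has a radius of about 5.3 nm and the fitted bending
rigidity is $\approx 14\,k_BT$, i.e. the chain model at $\chi N = 30$,
$f = 0.8$ is somewhat softer than the experimental membranes (reported
radii $\approx 8.5$ nm imply $\kappa \approx 35\,k_BT$).  The
inverse-square-root law $r = \sqrt{\kappa/2\sigma}$ itself is reproduced
essentially exactly (fitted exponent $-0.50$), and the double-membrane
tube shows the expected asymmetry: the inner tube is squeezed below the
single-tube radius while the outer one is pushed outward by the
intervening water layer.

## String method

Complicated membrane rearrangements admit no simple reaction coordinate,
so transformation pathways are computed with the simplified string
method over density configurations.  The metric is the volume-averaged
root-mean-squared change in local density summed over species
(`density_distance()`).  Free energy is a functional of the densities;
the conjugate fields are a saddle point, so descent is performed in
density space: each sweep (i) solves the constrained problem — iterate
the fields until the chain statistics reproduce the node's densities
(Anderson-accelerated, warm-started) — and (ii) moves each interior node
down the exchange component of the thermodynamic force,
$\tfrac12[\chi N(\phi_B - \phi_A) - (W_A - W_B)]$, which conserves total
density pointwise, with a trust-region cap on the per-step density
change.  Sweeps alternate with equal-arc-length reparametrization
(piecewise linear, iterated to a uniform-spacing fixed point); endpoints
stay fixed at independently converged SCFT states, and the reported
$F(\alpha)$ matches those endpoint free energies by construction.  The
reaction coordinate $\alpha$ is normalized cumulative arc length.

The machinery is validated where exhaustive search is possible: on an
analytic two-basin landscape (quartic double well, harmonic transverse
confinement, Gaussian ridge) the converged string's barrier agrees with
a flood-fill minimax search to better than 1% at 20 nodes, with the
error decreasing monotonically in node count.  At desk scale the SCFT
strings (translation paths, stalk formation) are qualitative: node
energies inherit the tolerance of the constrained solves
($\sim 10^{-5}$ in density residual), and publication-grade
minimum-free-energy paths of full fission pathways require cluster-scale
resolution out of scope here.

## Topology seeds and the stalk

`seed_topology()` builds tanh-profile tail-core ansätze (planar bilayer,
single/double tube, hemifusion stalk, pore, worm-like micelle, capped
tube) and converts them to initial fields.  The hourglass stalk between
two near-tensionless bilayers (midplane separation 2.6 $R_0$, neck radius
1 $R_0$, exploiting mirror symmetry about the midplane) converges to a
connected neck — tail density above 0.9 through the axis — and returns
to the same state after random field perturbations of amplitude
0.5 $k_BT$, while the disconnected two-bilayer configuration is a
separate, lower local minimum: hemifusion is metastable in this model,
consistent with the tail-heavy ($f = 0.8$, negative spontaneous
curvature) monolayers.

## Synthetic fluorometry

The fluorometry module implements the standard nanotube quantification:
$r = F_l / 2\pi D$ from the integral fluorescence per unit length and an
area calibration from a supported bilayer; $r = \sqrt{\kappa/2\sigma}$
from mechanics; inner-radius estimation for double-membrane tubes
($r_\mathrm{in} = r_\mathrm{out} - \text{thickness} - \text{gap}$, all
radii at bilayer midplanes, 5 nm thickness, 2 or 5 nm head-to-head gap);
and lamellarity classification from the bimodal $F_l$ distribution
(kernel-density mode finding with a two-means fallback, DM accepted only
at a center ratio of $2.0 \pm 0.3$).

`synth_line_scan()` generates the synthetic benchmark: thin cylindrical
shells of area $2\pi r$ per unit length (doubled for DM), blurred with a
Gaussian point-spread function and integrated numerically, with
multiplicative Gaussian noise on $F_l$.  It emulates idealized,
well-separated, in-focus tubes with uniform labeling; it does not emulate
out-of-focus light, background gradients, crossing tubes, or bleaching,
so classifier accuracy on real micrographs will be lower than the
$\geq 98\%$ achieved on the benchmark (SM/DM centers $m$ and $2m$, 10%
noise, $n = 200$).

## Problem sizes

The shipped tests and the acceptance pipeline run planar calculations on
160-cell grids ($dx = 0.05\,R_0$), tube calculations on 240-cell radial
grids, the stalk on a $40 \times 30$ axisymmetric half-domain
($dx = 0.125\,R_0$), and tension sweeps over five tensions spanning a
factor of four — sizes chosen so the whole pipeline completes in minutes
on one CPU while keeping the resolution-robustness checks (thickness and
tension move by less than 1% under refinement at the production spacing)
valid.

## Known limitations

* Mean-field theory: no composition fluctuations, no thermal undulations;
  $\kappa$ comes from the tube law, not from fluctuation spectra.
* One lipid species, neutral, with a single $\chi$; no explicit
  hydration-repulsion potential beyond solvent-mediated interactions, so
  intermembrane spacings in double-membrane systems are set by the chain
  model alone.
* The energy anchor (lipid molecular volume) is a modeling choice; all
  Dyn/cm and $k_BT$ outputs scale with it, and R0-unit results do not.
* Cartesian 3D grids are a coarse capability for exploratory
  (non-axisymmetric) states; production geometries are 1D/2D.
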