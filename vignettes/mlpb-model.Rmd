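---
title: "The modified Langevin-Poisson-Boltzmann model of a zwitterionic headgroup layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The modified Langevin-Poisson-Boltzmann model of a zwitterionic headgroup layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlpb)
```

## The physical problem

Glycerophospholipids such as DPPC carry no net charge, but their headgroup
is a zwitterion: a negative phosphate charge and a positive choline charge
separated by a fixed distance $D \approx 0.42$ nm. In a planar bilayer the
phosphate charges form, to a good approximation, a charged plane at $x = 0$
with surface charge density $\sigma = -e_0/a_0$, where $a_0$ is the area
per lipid. The choline charge protrudes into the electrolyte at a projected
distance between 0 and $D$, depending on how the headgroup dipole is tilted.
The electric field near this layer is strong enough (of order $10^8$–$10^9$
V/m) that water dipoles orient appreciably: the dielectric response
saturates and the local relative permittivity drops well below its bulk
value. Classical Poisson–Boltzmann theory with a constant permittivity
misses this entirely.

The MLPB (modified Langevin–Poisson–Boltzmann) model treats three couplings
self-consistently:

1. **Ions.** A monovalent symmetric salt at bulk density $n_0$ follows
   Boltzmann statistics,
   $n_\pm(x) = n_0 \exp(\mp e_0 \varphi \beta)$ with $\beta = 1/kT$, giving
   the ionic charge density
   $\rho_\mathrm{ions} = -2 e_0 n_0 \sinh(e_0\varphi\beta)$.
2. **Water.** Each water molecule is a point dipole $p_0$ at the centre of
   a sphere of permittivity $n^2$ ($n = 1.33$, the optical refractive
   index). With the cavity-field correction the polarization is
   $P(E) = n_{0w}\,\frac{2+n^2}{3}\,p_0\,\mathcal{L}(\gamma p_0 E \beta)$,
   where $\mathcal{L}(u) = \coth u - 1/u$ is the Langevin function and
   $\gamma = \tfrac32\,\frac{2+n^2}{3}$. The effective permittivity
   $$\varepsilon_r(E) = n^2 + \tfrac32\Bigl(\tfrac{2+n^2}{3}\Bigr)^2
     \frac{n_{0w} p_0^2 \beta}{\varepsilon_0}\,
     \frac{\mathcal{L}(u)}{u}, \qquad u = \gamma p_0 E \beta,$$
   decreases monotonically from the zero-field (Onsager) value — 78.5 at
   298 K with $p_0 = 3.1$ D and 55 mol/l water — toward $n^2$ at
   saturation.
3. **Headgroups.** The positive choline charge is smeared over
   $0 < x \le D$ with probability density
   $\wp(x) = \Lambda \exp(-e_0\varphi\beta)$, normalized so that
   $\frac1D\int_0^D \wp\,dx = 1$; the corresponding charge density is
   $\rho_\mathrm{Zw} = e_0 \wp /(D a_0)$, whose integral exactly cancels
   $\sigma$.

Poisson's equation then reads
$$\frac{d}{dx}\Bigl[\varepsilon_0\,\varepsilon_r(E)\,\frac{d\varphi}{dx}\Bigr]
  = 2 e_0 n_0 \sinh(e_0\varphi\beta)
  - \frac{e_0\,\exp(-e_0\varphi\beta)}
         {a_0 \int_0^D \exp(-e_0\varphi\beta)\,dx},$$
with $\varepsilon_0\varepsilon_r(0)\varphi'(0) = -\sigma$ at the plane and
$\varphi'(L) = 0$ at the far boundary $L = 12$ nm. The `sinh` term pins the
bulk reference $\varphi \to 0$, so the Neumann-only problem is well posed.

A finite-headgroup-volume variant replaces the Boltzmann density by the
lattice-statistics form
$\wp(x) = \Lambda\,\alpha e^{-e_0\varphi\beta}/(\alpha e^{-e_0\varphi\beta}+1)$,
where $\alpha$ is the ratio of headgroup volume to solution volume in the
headgroup region. It saturates where the Boltzmann form diverges; as
$\alpha \to 0$ it recovers the Boltzmann density and as $\alpha \to \infty$
(close packing) it flattens to $\wp \equiv 1$. Because no specific
$\alpha$ values are established for DPPC, `alpha` is a user-facing
parameter and comparisons across `alpha` are qualitative (limits and
ordering), exercised by `probability_density_comparison()`.

## Parameters

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `T` | temperature | 310 | K |
| `a0` | area per lipid | 0.48 (gel), 0.60 (liquid) | nm² |
| `D` | headgroup charge separation | 0.42 | nm |
| `p0` | water dipole moment | 3.1 | Debye |
| `salt` | bulk salt concentration | 0.1 | mol/l |
| `water` | bulk water concentration | 55 | mol/l |
| `n_refr` | optical refractive index | 1.33 | — |
| `alpha` | headgroup/solution volume ratio | none (Boltzmann) | — |
| `L` | domain length | 12 | nm |

The defaults are the DPPC reference conditions; `mlpb_preset()` switches
between the gel phase (below the 314 K main transition) and the
liquid-crystalline phase (above it). The transition temperature itself is
excluded — the model contains no phase-transition physics, so
`temperature_sweep()` refuses $T = 314$ K rather than silently picking a
phase.

## Numerical scheme

**Grid.** Two uniform zones: half the intervals on $[0, 2D]$, half on
$[2D, L]$ (about 13× finer in the headgroup zone for the default
geometry), with a node placed exactly at $x = D$ so the edge of the
headgroup support never falls inside a cell. The default is 4000 nodes;
doubling nests the grid, and the surface potential moves by less than
0.1 mV under doubling (checked in the tests), so the default is
effectively grid-converged.

**Discretization.** Conservative finite volumes: the flux
$F = \varepsilon_0\varepsilon_r\varphi'$ is evaluated at cell faces with
$\varepsilon_r$ computed from the face field $|\Delta\varphi|/h$.
Continuity of $\varphi$ and of $F$ at $x = D$ then holds by construction,
and the surface boundary condition enters as the known boundary flux
$F(0) = -\sigma$ — the field-dependent $\varepsilon_r(0)$ never needs to
be inverted explicitly.

**Iteration.** Damped Picard: each sweep freezes $\varepsilon_r(E)$ and
the normalization $\Lambda$ at the current iterate, Newton-linearizes the
`sinh` term, solves the resulting tridiagonal system (sparse LU via
`Matrix`), and relaxes with damping 0.25. The start is $\varphi \equiv 0$,
$\varepsilon_r \equiv$ Onsager, $\Lambda = 1$ — inside the attraction
basin for all DPPC parameter sets, which converge in roughly 90–140 sweeps
to the default tolerance of $10^{-9}$ V on the maximum node update
(well under a second per solve). Damping 0.25 trades speed for robustness
in the saturation regime, where an undamped update can overshoot into
Boltzmann-factor overflow; overflow is detected ($|e_0\varphi\beta| > 700$)
and reported as divergence rather than propagated as `Inf`.

**Langevin evaluation.** $\coth u - 1/u$ loses about six significant
digits near $u = 10^{-2}$ and all of them at $u \to 0$. Both
$\mathcal{L}(u)$ and $\mathcal{L}(u)/u$ therefore switch to 4-term Taylor
series for $|u| < 10^{-2}$; at that switch point the series truncation
error is below machine precision while the residual mismatch with the
naive form is about $2\times10^{-9}$ relative. The practical consequence:
the far-field permittivity approaches the Onsager value smoothly from
below instead of carrying $10^{-6}$-level cancellation noise, and
$\varepsilon_r(0) \equiv$ `onsager_permittivity()` exactly (same code
path).

**Quadrature.** $\Lambda$ and all profile integrals use composite
trapezoid rule on the grid restricted to $[0, D]$; with ~1000 fine-zone
points inside $D$ the normalization defect is below $10^{-8}$.

## The orientation angle

With the negative charge in the plane and a rigid charge separation $D$,
a positive charge at projected distance $x$ corresponds to a dipole tilt
$\omega(x) = \arccos(x/D)$ from the membrane normal. The package reports
the direct average
$$\langle\omega\rangle = \frac1D\int_0^D \wp(x)\,\arccos(x/D)\,dx,$$
which is 1 radian (57.2958°) exactly for a uniform density and increases
as the density piles up at the plane (headgroups lying flatter). An
alternative reduction — averaging $\cos\omega$ first and taking
$\arccos$ of the mean — is available via the `convention` argument; the
direct average is the default because it reproduces the reference value
69.36° for the DPPC liquid phase (the package computes 69.34°). The
$\arccos$ weight has a square-root-singular slope at $x = D$, which
limits trapezoid accuracy there to about $10^{-5}$ relative — far below
the 0.01° reporting precision.

By default $\langle\omega\rangle$ is computed from the Boltzmann (point-like)
density even when `alpha` is set, since the reference angle is a result of
the point-like model; `form = "lattice"` selects the finite-volume density.

## What the solution looks like

Two features deserve comment because they are easy to mistake for bugs:

* The potential is **not** monotone in sign. It is strongly negative at
  the plane (−62 mV gel, −54 mV liquid), crosses zero *inside* the
  headgroup region (near $x \approx 0.25$ nm in the gel run), overshoots
  to a few millivolts positive just beyond $D$ — the classic signature of
  a dipole layer — and then decays to zero with the bulk Debye length
  (0.96 nm at 298 K, 0.1 M). Counter-ions therefore dominate only where
  $\varphi < 0$; beyond $D$ the co-ions are in slight excess.
* The Boltzmann probability density mirrors the potential exactly, so the
  tiny potential maximum just inside $D$ produces a correspondingly tiny
  ($\sim 10^{-4}$) uptick in $\wp$ there; the density is otherwise
  strictly decreasing away from the plane.

## Validation strategy

The solver is never trusted against itself:

* With the permittivity frozen and the headgroup term off, it must match
  the closed-form Gouy–Chapman double layer (via the Grahame equation) to
  better than 0.5 mV everywhere; the observed agreement is ~$10^{-3}$ mV.
* Pointwise physics (Langevin function, polarization, permittivity, ion
  statistics) is checked against 30-digit arbitrary-precision evaluations
  frozen into the tests, and against closed-form normalizations for
  exponential densities.
* Conservation is checked globally: the converged solution satisfies
  electroneutrality $\sigma + \int(\rho_\mathrm{Zw} +
  \rho_\mathrm{ions})\,dx = 0$ to ~$10^{-13}$ relative (the conservative
  discretization makes this exact up to the linear-solver tolerance).
* The reference observables (surface and far-field permittivity, surface
  potential, orientation angle, at both DPPC phase points) are recomputed
  end-to-end in `tests/testthat/test-acceptance.R` and by
  `scripts/acceptance.R`.

## Limitations

The model neglects the finite volume of ions and water (the water number
density is uniform at its bulk value), treats the membrane as a perfectly
planar, laterally uniform charged plane, and contains no chain-melting
physics — the gel/liquid difference enters only through $a_0$, which is
why the orientation angle is flat within each phase and jumps at the
transition. The lattice-statistics correction applies to the headgroups
only, not to the ions. All geometry is 1-D and static; nothing here
describes lateral correlations, headgroup dynamics, or specific ion
binding.
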