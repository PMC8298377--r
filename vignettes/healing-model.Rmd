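---
title: "A coupled chemo-mechano-biological model of damage-induced healing in soft tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled chemo-mechano-biological model of damage-induced healing in soft tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanoheal)
```

## The model

`mechanoheal` simulates what happens to a soft collagenous tissue after a
mechanical overload: collagen molecules are damaged (interstrand
delamination, a plastic sliding of one strand of the triple helix), the
damaged material recruits matrix metalloproteinases (MMP) that clear it,
growth factors (GF) arrive with a delay and deposit new collagen, and the
net change of tissue mass appears at the continuum scale as volumetric
growth. The package couples four ingredient models.

**Kinematics.** The deformation gradient of the mixture is split
multiplicatively, $F = F_e^c F_r^c F_p^c$ for collagen and $F = F_e^m$ for
the non-collagenous matrix (the matrix deforms purely elastically). The
plastic part $F_p^c = \lambda_p M_0 + \lambda_p^{-1/2}(I - M_0)$ and the
remodeling part $F_r^c$ (same form, built on the mapped fiber direction)
are unimodular rank-one modifications of the identity: they stretch along
the fiber and contract transversely so that damage and remodeling are
isochoric — any volume change is reserved for growth. Because the fiber
direction is an eigenvector of both inelastic tensors, the fiber stretch
itself factorizes, $\lambda = \lambda_e \lambda_r \lambda_p$.

**Constitutive model.** The free energy per unit reference volume is
$\Psi = \rho_0^c W^c + \rho_0^m W^m + \rho_0 W^L$ with mass-specific
energies (J/kg) weighted by reference densities:
an exponential tension-only fiber law
$W^c = \tfrac{k_1}{2k_2}(e^{k_2\langle I_e^c-1\rangle^2}-1)$ in the *full*
anisotropic invariant $I_e^c = \lambda_e^2$; an isochoric neo-Hookean
matrix law $W^m = \tfrac{\mu}{2}(\bar I_1 - 3)$ (volume changes do not
load the matrix, so growth happens against the fiber and boundary
stiffness only); and a quadratic penalty
$W^L = \tfrac{\kappa}{2}\,(J - \rho_0/\rho_0(0))^2$ that enforces
incompressible growth — the volume ratio tracks the reference-density
ratio. Stresses are $S = 2\,\partial\Psi/\partial C$ at frozen internal
variables (analytic, chain rule through the inelastic maps) and
$\sigma = J^{-1} F S F^T$.

**Damage and remodeling.** The damage drive is the history maximum of the
tissue fiber stretch divided by the current remodeling stretch,
$\lambda^c_{\max}(t) = \max_\tau \lambda(\tau) / \lambda_r(t)$. Above a
threshold $\bar\lambda_p$ the damage variable is
$d = \min\{1, m_p\langle\lambda^c_{\max}-\bar\lambda_p\rangle\}$, held
monotone; the associated flow rule
$\dot\lambda_p = d\,\dot\lambda^c_{\max}/\lambda_e$ (active only under
fiber tension) converts damage growth into permanent stretch and is
capped where $\lambda_e = 1$. The literal linear law would return zero
once $d = 1$; the clamped, monotone form is used instead, consistent with
the stated range $d\in[0,1]$ and irreversibility. Remodeling relaxes the
elastic fiber stretch toward the deposition prestretch,
$\dot\lambda_r = k_{rem}(\lambda_e - \lambda_{pre})/(\lambda_{pre}-1)$.

**Biology and growth.** At the start of healing the collagen density is
split into damaged and intact pools by the final damage value,
$\rho^{cd*}_0 = d^*\rho^{c*}_0$. Damaged collagen produces MMP
($\dot M = m_1 \rho^{cd}_0/\rho^{c*}_0 - m_2(M-M_0)$), MMP removes it at
a saturating rate (bounded by $k_{d1}$), the decaying window average of
the MMP excess
$I_M = \big(\tfrac{1}{t-t^*}\int_{t^*}^t (M-M_0)\,d\tau\big)
e^{-(t-t^*)/t_{decay}}$ drives GF
($\dot G = g_1 I_M - g_2(G-G_0)$), and GF deposits intact collagen at a
saturating rate (bounded by $k_{i1}$). The matrix density is constant.
Homeostasis ($M=M_0$, $G=G_0$, no damaged pool) is an exact fixed point —
by construction also in floating point, which is why the accumulator
stores the *excess* integral $\int(M-M_0)d\tau$ rather than $\int M\,
d\tau$ (the two are algebraically equivalent in the signal).

## Staggering and time integration

Damage acts over seconds, healing over months, so the phases are run
consecutively at each Gauss point: a *prestretch* phase (remodeling only),
a *damage* phase (plastic set evolves; biology and growth frozen), and a
*healing* phase (biology, growth and remodeling evolve; plastic set
frozen, pools initialized from $d^*$). Phase boundaries belong to the
later phase. All internal variables advance by backward Euler; the scalar
implicit equations use Newton with relative tolerance $10^{-12}$ (at most
50 iterations, bisection fallback). Remodeling is left active during the
60-s damage phase — its effect there is $O(10^{-5})$ — with a switch to
disable it. Prestretch initialization defaults to the closed form
$\lambda_r = \lambda/(\lambda_p\lambda_{pre})$ (the steady state of the
remodeling law); rate-form integration is available as an option.

Default step sizes: 0.25 s in the damage phase (240 steps over 60 s) and
0.1 day in the healing phase, both configurable. The tests verify
first-order self-convergence: halving the healing step changes the
one-year collagen mass by well under 0.5%, and the backward-Euler
trajectory agrees with an adaptive stiff integrator (`deSolve::lsoda`) to
a few parts per thousand.

## The mixed finite element

Growth makes the volumetric response the interesting part, so the solver
uses a three-field Hu–Washizu form of the volumetric term: trilinear
displacements plus an element-wise constant dilatation $\theta$ and
pressure multiplier $p$ (an H1-P0 element). Stationarity gives
$p = \kappa(\theta - \bar g)$ and $\theta = \langle J\rangle$ (density-
weighted element averages); both are condensed at element level, so the
global Newton system is displacement-only. Quadrature is 2×2×2. The
consistent material tangent $2\,\mathrm{d}S/\mathrm{d}C$ is computed by
central finite differences of the stress with the internal variables
re-solved at each perturbed state (step $10^{-6}\cdot\mathrm{tr}(C)/3$);
tests compare it against Richardson-extrapolated directional derivatives
computed by independent code. Element assembly and the Gauss-point update
run in compiled code, mirrored line by line by the pure-R material-point
functions; the two paths agree bitwise in tests, and a single-element
mixed solve reproduces the material-point driver to $10^{-6}$.

The global Newton iteration converges on a $10^{-8}$ relative residual
reduction with an absolute floor of $10^{-9}$ of the internal-force scale
(hold steps start at machine-precision residuals that cannot shrink
further); failed steps are bisected up to four times. Meshes are
structured hexahedral plates with optional geometric grading toward the
loaded corner (ratio 0.7 between neighboring element sizes in the
indentation study — the reference computation states only that the loaded
region is refined). The indentation pressure
$p(r,t)=\bar p(t)(1 - r/r_p)$ for $r \le r_p = 1$ cm is applied as a dead
load on the reference top surface (a follower flag was considered
unnecessary at these rotations, and the reference computation does not
specify follower behavior). After prestretch, the essential boundary
conditions on the outer faces are swapped for the equivalent nodal
reactions, leaving the plate in equilibrium and free to grow
anisotropically.

## Parameters

Units are SI throughout; 1 year = 365 days = 3.1536e7 s converts the
rates quoted per year ($k_{rem} = 0.8$/yr, $t_{decay} = 0.5$ yr). One
published table lists the MMP production constant $m_1$ as kg/m³; the
rate equation requires kg/(m³ s), which is adopted everywhere (it also
reproduces the stated MMP fixed point $M_0 + m_1/m_2 = 9.6\times10^{-5}$
kg/m³). Presets: `params_species()` (biology study),
`params_biaxial()` (6×3×0.225 mm quarter sample, $m_p = 2.5$,
$\bar\lambda_p = 1.3$, $\kappa = 10^7$ J/kg, elevated deposition
$k_{i1} = 2\times10^{-4}$ kg/(m³ s)) and `params_indentation()`
(6×6×1.2 cm quarter plate, $m_p = 4.5$, $\bar\lambda_p = 1.1$,
$\kappa = 10^8$ J/kg, faster GF dynamics). The biaxial loading waveform
is not fully specified in the source study beyond "two cycles" with
maxima 1.83 and 1.93 within 60 s; it is realized as four equal 15-s
linear ramps (up to 1.83, back to 1.34, up to 1.93, then either back to
1.34 or held, selecting the healing configuration). Since the damage
drive depends only on the stretch maxima, the per-cycle collagen-stretch
maxima and $d^*$ are insensitive to this choice.

## What the studies do and do not show

The built-in studies generate all inputs programmatically: there is no
measured data anywhere, and every run is deterministic. The species study
fixes $d$ and integrates the biology at one material point; the biaxial
study is a homogeneous single-element problem; the indentation study is
the only spatially heterogeneous case. Passing tests therefore
demonstrate internal consistency of the coupled model and solver — not
agreement with any measured healing tissue. Parameters of the species
equations are, as in the source study, plausibility-scaled rather than
fitted.

Two published scalar outcomes deserve a note. First, the end-of-damage
value $d^*$: the damage law applied to the published collagen-stretch
maximum 1.53 gives $2.5\,(1.53-1.3) = 0.575$, while 0.56 is printed; the
two are consistent only to about 3%, so checks on $d^*$ use a 5% band.
Second, the two published thickness increases after a year of biaxial
healing (44.01% prestretched, 35.5% at maximum stretch) cannot both
follow from the printed equations: with both in-plane stretches clamped,
the penalty ties $J$ to $\rho_0(t)/\rho_0(0)$ to within $\sim10^{-6}$, so
the thickness ratio equals the density ratio in *either* configuration —
the model forces the two percentages to be equal, and integrating the
printed biology with the printed parameters puts their common value near
+115% (confirmed by two independent integrators). The package reports
what the equations produce; `run_biaxial()` exposes the full history so
the constraint can be inspected directly.

Problem sizes used in the test-suite runs are deliberately modest — the
single-element biaxial problem at default steps, the indentation study at
8×8×4 or 6×6×3 meshes with coarsened healing steps (20 × 22 × 8 with
0.1–1-day steps reproduces the reference resolution when more time is
available). At reduced meshes the indentation checks are qualitative
(damage localized under the load, thickness strain at the center probe
first negative from removal, then crossing zero and ending positive, and
growth ordered $z > y > x$ by compliance), since the coarse cone
resolution dilutes the local stretch maxima.

## Known limitations

One fiber family, no dispersion; no diffusion of MMP/GF (purely local
biology); no mechano-feedback onto the production rates; no viscous or
rate effects in damage; plastic stretch is permanent (healing does not
reverse it); the indentation is a prescribed pressure, not a contact
problem. These mirror the scope of the modeling framework the package
implements.
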