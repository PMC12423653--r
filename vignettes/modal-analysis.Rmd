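---
title: "Modal analysis of active swimming filaments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modal analysis of active swimming filaments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimmodes)
```

## The physical model

A slender flexible filament of length $L$ beats in a Stokes flow, driven by
an internal moment distribution $m(s,t)$ — the continuum description of a
spermatozoon flagellum, and equally of sperm-like artificial swimmers driven
by magnetic beads or cultured muscle cells. Three forces balance
instantaneously at every point: resistive-force-theory drag (anisotropic,
with normal and tangential coefficients $c_\perp$, $c_\parallel$), passive
bending elasticity (modulus $A$), and the active forcing. After
non-dimensionalizing lengths with $L$, time with the inverse beat frequency
$1/\omega$ and moments with $A/L$, a single dimensionless group remains, the
sperm number
$$ \mathrm{Sp} = L \, (\omega c_\perp / A)^{1/4} = L / l_e, $$
the filament length in units of the elastic penetration length $l_e$ — how
many "damping lengths" of elastic bending waves fit on the filament.

For small forcing amplitude $\epsilon$, the tangent angle linearizes about a
straight filament, and the thrice-integrated angle field $\Psi$ obeys the
forced **hyperdiffusion equation**
$$ \mathrm{Sp}^4 \, \Psi_t + \Psi_{ssss} = m, \qquad
   \Psi_t = \Psi_{st} = 0 \ \text{at } s = 0, 1, $$
whose boundary conditions express that a free-ended filament can exert no
force or torque at its tips. For single-frequency forcing
$m = \mathrm{Re}[f(s) e^{-i\phi(s)} e^{it}]$ the response is
$\Psi = \mathrm{Re}[\Phi e^{it}]$ with
$\mathrm{Sp}^4 i \Phi + \Phi'''' = f e^{-i\phi}$, solved exactly by the
Green's function $G(s;\xi)$ built from the four natural modes $e^{ks}$,
$k^4 = -\mathrm{Sp}^4 i$ (`build_greens()`, `eval_greens()`).

Because the swimmer is force- and torque-free, its leading-order
time-averaged swimming speed is a *bilinear* functional of the forcing
magnitude: with the **reduced speed**
$U = \tfrac{2 c_\parallel}{c_\perp - c_\parallel}\langle U^{(2)}\rangle$,
$$ U = \int_0^1\!\!\int_0^1 f(\xi_1)\, G_{\mathrm{swim}}(\xi_1,\xi_2)\,
       f(\xi_2)\, d\xi_2\, d\xi_1, $$
where the real symmetric kernel $G_{\mathrm{swim}}$ is assembled from the
arc-length derivative of $G$ and the phase function (`compute_kernels()`,
`speed_quadrature()`). Positive $U$ means tip-first swimming; converting to
metres per second multiplies by
$\epsilon^2 \tfrac{c_\perp - c_\parallel}{2 c_\parallel} L \omega$
(`redimensionalize()`).

## The modal decomposition

$G_{\mathrm{swim}}$ has an orthonormal eigenbasis $g_n$ with real
eigenvalues $\lambda_n$, and $U = \sum_n a_n^2 \lambda_n$ for
$a_n = \int f g_n$. The eigenfunctions are exactly the stationary profiles
of $U$ under the unit mean-square constraint $\int f^2 = 1$, so the largest
positive eigenvalue *is* the best achievable speed under that budget. The
kernel is discretized on the midpoint grid $\xi_n = (2n-1)/2N$ and
eigen-solved as a symmetric matrix (`eigendecompose()`), with matrix
eigenvalues divided by $N$ to approximate operator eigenvalues.

The default $N = 100$ resolves every quantity reported here: the leading
six eigenvalues move by less than $10^{-4}$ relative when $N$ is raised to
400 (asserted in the test suite), because the leading eigenfunctions
oscillate on the scale of the filament itself, not of the grid.

## What is computed analytically, and numerical choices

**Monophasic forcing** ($\phi \equiv 0$, the regime of magnetically or
muscle-actuated artificial swimmers) is special: the kernel reduces to its
symmetric part and exactly **four** eigenvalues are non-zero, in pairs
$\{\lambda_+, \lambda_-, -\lambda_-, -\lambda_+\}$ whose negative members
belong to reflected eigenfunctions. `analytic_system()` assembles this
four-mode eigenproblem exactly: the symmetric/antisymmetric natural-mode
pair $(f_s, f_a)$, eight $4\times4$ complex boundary solves for the
auxiliary fields, the four coupling constants $E_3$, and a real
$4\times4$ eigenproblem.

Numerical choices that matter:

* **Anchored exponentials.** Natural modes grow like
  $e^{0.92\,\mathrm{Sp}\, s}$; every mode is stored as
  $c\,e^{k(s-a)}$ with the anchor $a$ at the end where the mode peaks, so no
  growing exponential is ever evaluated and all linear solves stay well
  conditioned up to $\mathrm{Sp} = 30$ (the certified range; parameter scans
  use $\mathrm{Sp} \ge 0.05$).
* **Pair-structured eigensolve.** The $4\times4$ matrix couples the
  symmetric and antisymmetric coefficient pairs off-diagonally, so
  $\lambda^2$ are eigenvalues of a $2\times2$ product. Solving in that form
  enforces the exact $\pm$ pairing. Below $\mathrm{Sp} \approx 1$ the
  subdominant $\lambda_-$ falls under $\sim 10^{-2}\lambda_+$ and loses
  significance to cancellation; no reported quantity depends on it there.
* **Third-derivative quadrature.** $\partial_s^3 G$ has a unit jump at the
  source. When reconstructing $\Psi_{sss}$ by quadrature over source
  points, the sampled step function is replaced by its exact integral
  (a closed-form correction), restoring second-order accuracy. At the
  source point itself the right-side limit is returned.
* **Exact torque integrals.** The identity "the leading-order global torque
  vanishes at all times" is verified with closed-form arc-length integrals
  of the Green's-function modes rather than quadrature, so the test
  tolerance can sit at $10^{-8}$ of the beat amplitude.
* **Discrete actuators are never smeared.** Point-moment actuators enter
  speed formulas through exact kernel / eigenfunction evaluation at the
  actuator coordinates.
* **Sign conventions.** Eigenfunctions are normalized to unit mean square;
  the sign is fixed so the front half integrates positive (numeric modes:
  largest-magnitude sample positive, ties to the smaller index). These
  conventions make $g_s = g_+(s) + g_+(1-s)$ positive and
  $g_a/g_s$ strictly decreasing, the orientation used by the optimizers.
* **Internal consistency over printed intermediates.** Two printed
  intermediate formulas of the source derivation are inconsistent with the
  derivation's own eigen-relation (the sign of the auxiliary field that
  carries the eigenvalue, and one term of the sign-switch cutoff
  equation). The package follows the forms that the independent
  finite-difference route (below) confirms; trusting the printed variants
  reflects every optimal design about the midpoint or shifts the cutoff.

## Verification strategy

The package carries its own independent oracle: `bvp_oracle()` discretizes
the time-harmonic boundary-value problem with second-order finite
differences (banded sparse solve), never touching the analytic Green's
function. The central identity — the kernel double integral equals
$-2\int_0^1 \langle \Psi_{sss}\Psi_{sst}\rangle\, ds$ computed from the
reconstructed motion (`speed_time_average()`) — is asserted to $10^{-4}$
relative on seeded smooth random profiles, and the analytic
$\lambda_\pm$ must match the $N=100$ numeric eigendecomposition to
$10^{-5}$ relative. The 256-sample uniform time grid makes the period
average spectrally exact.

The "random smooth profile" generator draws low-order Fourier coefficients
uniformly from $[-1, 1]$ under a fixed seed. It emulates smooth,
filament-scale forcing profiles; it does not probe discontinuous or
near-singular forcing, where midpoint kernel quadrature degrades to first
order — piecewise-constant designs are therefore scored through the exact
analytic integrals of the eigenmodes, and a kernel cross-check aligns the
discontinuity with a grid-cell boundary.

## Worked example: designing a monophasic swimmer

```{r design}
sys <- analytic_system(4.7)      # Sp = 4.7 maximizes lambda+
c(lambda_plus = sys$lambda_plus, lambda_minus = sys$lambda_minus)

# best piecewise designs under f in {0, 1} and {-1, 1}
binary_cutoff(sys)$configuration$cutoff
ternary_cutoff(sys)$speed_factor

# a single point actuator with the whole unit forcing budget
res <- optimize_actuators(sys, m = 1)
c(location = res$configuration$actuators$xi, SF = res$speed_factor)
```

The speed factor (SF) divides a design's reduced speed by $\lambda_+$ at
the same sperm number: 100% is what unit-mean-square eigenfunction forcing
achieves. Under a *total* forcing budget $\int |f| = 1$ the eigenfunction
manages `r round(eigenfunction_budgets(analytic_system(4.7))$sf_unit_l1, 1)`%,
while concentrating the whole budget at one point near a third of the way
along the filament almost doubles that — distributing forcing is
counterproductive for these swimmers, in sharp contrast to the fully
distributed forcing of biological flagella.

## Travelling-wave forcing

With $\phi = 2\pi k \xi$ the kernel describes a backwards-travelling wave
of forcing with $k$ wavelengths on the filament. `scan_travelling_wave()`
maps the largest positive eigenvalue over the $(\mathrm{Sp}, k)$ plane
(defaults $\mathrm{Sp} \in [0.05, 6]$ step 0.05, $k \in [-3, 3]$ step 0.02,
chosen to cover the optimal ridge near $k = 0.72$ and the forward-wave
local optimum near $k = -1.5$); the scan reuses the per-$\mathrm{Sp}$
kernel parts across $k$. Ten modes reproduce the speed of smooth forcing
profiles to 0.01% at the near-optimal point $(k, \mathrm{Sp}) = (0.72, 3)$.
Behaviour below $\mathrm{Sp} = 0.05$ is numerically delicate and
deliberately uncertified.

## Limitations

The linearized model omits the head and payload hydrodynamics of real
swimmers, three-dimensional and helical beating, tension (absent at leading
order), and any feedback of amplitude on forcing; accuracy for order-one
forcing amplitudes is empirically reasonable but not guaranteed. The
relative error of a truncated modal sum is undefined for profiles whose
exact speed vanishes (uniform monophasic forcing — the scallop theorem),
and `truncation_error_curve()` refuses them rather than returning NaN.
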