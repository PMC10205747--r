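---
title: "Models and numerical methods in hemoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in hemoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemoflow)
```

`hemoflow` implements the computational layer that surrounds a 3D
patient-specific aortic flow simulation: boundary-condition construction
and calibration on the way in, and field reduction to clinical indices on
the way out. This vignette explains each model, the choices behind the
defaults, and what the synthetic validation data do and do not demonstrate.

## The inlet waveform

The inlet velocity is an idealised half-sine ejection pulse: during systole
$V(t) = V_0 \sin(\pi t / D)$, and zero during diastole. The default
parameters — peak velocity $V_0 = 96.1$ cm/s, ejection duration
$D = 0.273$ s, cycle length $T = 0.731$ s — describe a single adult
post-repair case whose waveform was measured by pulsed-wave Doppler; they
are configuration values, not population statistics.

Descriptions of this waveform sometimes express the ejection time as a
fraction of the cycle rather than a duration in seconds, and the two
readings differ (an ejection window of 0.273 s versus
$0.273 \times 0.731 = 0.1996$ s). We treat 0.273 as a duration in seconds —
a 37% systolic fraction at 82 bpm, which is physiologically ordinary,
whereas a 0.20 s ejection at this rate would be short — and expose the
fractional convention through `cardiac_timing(ejection_fraction = )` so
either reading is expressible.

Volumetric flow is obtained with a plug (flat) velocity profile,
$Q(t) = V(t) A$. The inlet area is a free configuration parameter with
default 4.9 cm², a typical adult ascending-aorta lumen; no patient area
measurement backs it, and analyses that depend on absolute flow should set
it explicitly. Sampling defaults to $\Delta t = 2$ ms, the time step at
which transient solver output is commonly written; the grid always includes
the cycle endpoint so that sampled series are exactly periodic.

## Carreau–Yasuda rheology

Blood shear-thins. The Carreau–Yasuda law interpolates between a low-shear
plateau $\mu_0 = 0.0220$ Pa·s and a high-shear plateau
$\mu_\infty = 0.0022$ Pa·s with time constant $\lambda = 0.11$ s, Yasuda
exponent $a = 0.644$ and power-law index $m = 0.392$ — standard whole-blood
constants. The implementation evaluates $(1+(\lambda\dot\gamma)^a)^{(m-1)/a}$
through `log1p`, switching to a pure log-space form for
$\lambda\dot\gamma > 10^8$ so that extreme shear rates reach the
$\mu_\infty$ plateau without floating overflow. Setting
$\mu_0 = \mu_\infty$ recovers a Newtonian fluid exactly. Density
(1056 kg/m³) is carried with the rheology because the Womersley generator
needs both.

## Three-element Windkessel models and their calibration

Each outlet is a resistance–compliance–resistance (RCR) circuit:
$$C \frac{dP_c}{dt} = Q - \frac{P_c - P_v}{R}, \qquad P = P_c + Q\,r.$$

**Integration.** Over one sampling interval the ODE is linear with the
outflow held piecewise-linear, so the update is evaluated in closed form
(exponential integrator). This is exact for the interpolated forcing,
unconditionally stable, and indifferent to the stiffness ratio
$\Delta t / RC$ — no adaptive stepping is needed at the 2 ms grid. Periodic
steady state is declared when consecutive cycles agree within 0.05 mmHg
everywhere (configurable; the tuner uses 0.01 mmHg), with a minimum of five
burn-in cycles. Initialising the capacitor at the resistive mean pressure
makes convergence fast — typically under fifteen cycles.

**Tuning.** Given systolic/diastolic targets (defaults 120 / 77.5 mmHg) and
a periodic outflow, `wk_tune()` proceeds in the standard two stages:

1. the total resistance is fixed by the mean-pressure balance
   $R + r = (\mathrm{MAP} - P_v)/\bar Q$ with the classical estimate
   $\mathrm{MAP} = P_{dia} + (P_{sys}-P_{dia})/3$, and the proximal share
   starts at the characteristic-impedance convention
   $r/(R+r) = 0.056$;
2. the compliance is bracketed and bisected on simulated pulse pressure,
   then a damped Newton iteration on the pair (proximal share, compliance)
   — finite-difference Jacobian, total resistance held fixed — drives both
   pressure extremes onto their targets, by default to within 0.05 mmHg.

The venous reference pressure defaults to 0 mmHg. Infeasible targets (a
pulse pressure outside what any compliance can produce for the given flow)
are reported with the attainable range rather than silently approximated.
The tuner returns a classed model object with the usual
`print`/`summary`/`coef`/`predict`/`simulate`/`residuals`/`plot` methods,
so a tuned outlet can be interrogated like any fitted model. A reference
set of tuned parameters for the four aortic outlets (brachiocephalic
trunk, left common carotid, left subclavian, distal aorta) is bundled as
`reference_windkessel()`.

## Synthetic fields with analytic ground truth

The package validates its post-processing against fields whose answers are
known in closed form, standing in for solver output:

* **Womersley pipe flow** — the exact pulsatile solution in a rigid
  circular pipe, any number of harmonics plus a steady Poiseuille part.
  Harmonic amplitudes follow the same sign convention as the steady
  gradient (amplitudes of $-dp/dz$), so the low-frequency limit is in phase
  with quasi-steady Poiseuille flow. Velocity and wall shear are evaluated
  from the analytic profile; the wall series carries the axial shear vector
  with inward surface normals. Complex $J_0$/$J_1$ are computed by the
  ascending power series in complex double arithmetic; along the Womersley
  ray the cancellation at the cap $\alpha = 50$ costs about five digits,
  leaving ~$10^{-11}$ relative accuracy, far below anything the quadrature
  downstream resolves. Larger Womersley numbers are refused rather than
  extrapolated.
* **Rigid-body vortices** — $v = \omega\,\hat a \times x$, whose gradient
  tensor has the complex pair $\pm i\omega$: exact ground truth for
  swirling strength.
* **Branching networks** — outlet flows as fixed fractions of an inlet
  waveform, with the undistributed remainder recorded, plus optional
  seeded multiplicative Gaussian noise.

These fields validate the *estimators* — quadrature, gradients,
eigenstructure, bookkeeping. They are laminar, axisymmetric or affine, and
rigid-walled; they do not exercise turbulence, geometric complexity,
moving walls or measurement artefacts, so passing tests demonstrate
correctness of the analysis stages, not fidelity of any particular 3D
simulation.

## Wall-shear indices

TAWSS, OSI and HOLMES are computed per node with composite trapezoidal
integration on the stored grid — trapezoid rather than a higher-order rule
because solver exports are uniform but user data may be ragged, and the
kinked integrand $|\vec\tau(t)|$ caps the attainable order anyway. At the
solver-native 366 steps per cycle, TAWSS and OSI agree with 10×-refined
quadrature to better than 0.1%. Where a series spans several whole cycles,
the last cycle is used — the convention for periodic-steady transient runs.
OSI is defined as 0 at nodes with TAWSS below $10^{-12}$ Pa (the index is
0/0 there; no shear means no oscillation to report), and roundoff is
clamped so OSI always lies in $[0, 0.5]$.

Percent-difference maps (e.g. compliant vs rigid-wall HOLMES) use the
reference case as denominator, mask nodes whose denominator is below a
configurable threshold instead of letting them blow up, and summarise the
fraction of nodes beyond ±5/±10/±20% — the three colour scales conventional
for wall-motion sensitivity maps.

## Swirling strength

The velocity-gradient tensor is estimated either by second-order central
differences on a structured lattice, or — for arbitrary point clouds — by a
per-point linear least-squares fit over the $k$ nearest neighbours
(default $k = 12$), which is exact on affine fields. When a neighbourhood
is rank-deficient (distance ties on lattices, locally flat shells), the
neighbourhood is widened geometrically before a degeneracy error is
raised; genuinely coplanar clouds still fail loudly, naming the point.

Swirling strength $\lambda_{ci}$ is the imaginary part of the complex
eigenpair of the tensor, obtained from the characteristic cubic in closed
form after scaling by the largest entry; within $10^{-12}$ of the
real/complex discriminant boundary the code falls back to a general
eigensolver. Against a brute-force `polyroot` oracle on random tensors the
agreement is better than $10^{-9}$ relative to the tensor norm, and the
measure is invariant under orthogonal conjugation to the same tolerance.

Plane statistics follow the convention of summarising a vessel by
cross-sections: $n$ planes (default 38) equally spaced by arclength along
a centerline, normals along the local tangent, each plane sampling the
points within a slab of half-width equal to half the plane spacing
(nearest-sample slabs rather than interpolation — cheap, unbiased for the
plane *mean*, and robust on unstructured clouds). Per-plane means use the
unweighted arithmetic mean; TASS is the trapezoidal time average per
plane; the cross-plane mean-SS series is normalised by its own cycle
maximum. That normalisation constant is a convention — the raw series is
always returned alongside, so any alternative scaling can be recovered.
Empty slabs yield a missing value with a warning and are excluded from
cross-plane means.

## Wall mechanics

Only point-wise constitutive evaluations are provided — no structural
solve. Von Mises stress is computed from the symmetric Cauchy tensor
(symmetry enforced to $10^{-9}$ relative) and verified against the
principal-stress formulation; it is hydrostatic- and rotation-invariant by
construction. The two-parameter Mooney–Rivlin law
$W = A(I_1 - 3) + B(I_2 - 3)$ with the aortic-wall constants
$A = 0.1740$, $B = 1.8810$ MPa is evaluated in its incompressible uniaxial
closed form $\sigma = 2(\lambda^2 - \lambda^{-1})(A + B/\lambda)$ — the
model is commonly stated without a volumetric term, and artery wall is
nearly incompressible. The small-strain shear modulus is $2(A+B)$.
Displacement fields reduce to per-region max/mean magnitudes at selected
times.

## Flow splits

Systolic outlet fractions integrate each outlet flow and the inlet over the
ejection window — $[0, 0.273]$ s by default, since the half-sine inlet is
identically zero outside it — and are deliberately *not* renormalised to
100%: truncated minor branches and wall motion make published split tables
sum below 100%, and hiding that residual would hide information. Relative
changes are signed ($100\,(\mathrm{post}-\mathrm{prior})/\mathrm{prior}$)
and rounded only at presentation.

## Problem sizes and determinism

The test suite runs synthetic problems sized for interactive use: field
lattices of order $10^2$–$10^3$ points, cycles of 40–366 time steps,
Windkessel runs of up to a few hundred cycles of 367 samples, and
1000-tensor eigenvalue sweeps — about twenty seconds in total. All
stochastic elements (noise injection, random test tensors) are driven by
explicit integer seeds, and `run_pipeline()` outputs are a pure function of
its configuration and seed, with a provenance log recording both.

## Known limitations

* No 3D flow or structural solve: fields come from a solver or from the
  analytic generators; the package post-processes them.
* The Windkessel tuner calibrates one outlet against one flow waveform;
  simultaneous multi-outlet tuning under a shared inlet constraint is the
  user's composition.
* The Womersley generator assumes a rigid straight pipe and laminar flow;
  its Womersley number is capped at 50.
* The half-sine inlet is a one-parameter idealisation; multi-harmonic
  physiological waveforms are not modelled.
* Spring-supported wall boundary conditions and stent mechanics, which a
  full FSI study would include, have no desk-scale counterpart here and
  are limited to configuration metadata.
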