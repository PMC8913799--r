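---
title: "Modelling and inverting skin elasticity with a nearly incompressible transversely isotropic material"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and inverting skin elasticity with a nearly incompressible transversely isotropic material}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitioce)
```

## The model

Skin's dermis is dominated by collagen fibers aligned along Langer's lines,
making it mechanically anisotropic, and like all soft tissue it is nearly
incompressible. `nitioce` models it as a **nearly incompressible transversely
isotropic (NITI)** solid: one isotropy plane, one symmetry (fiber) axis, and
longitudinal moduli ($\lambda$-scale, GPa) vastly exceeding shear moduli
(kPa-scale). In Voigt form the stiffness matrix is the isotropic Lamé matrix
with three modifications: an out-of-plane shear modulus $G$ replacing $\mu$ in
the 44/55 slots, and tensile couplings $Q_1$, $Q_2$ entering the 13/23 and 33
slots. In the incompressible limit every in-scope observable depends on
$Q_1, Q_2$ only through the tensile-anisotropy parameter
$\delta = Q_2 - 2Q_1$, so the parameter set is $(\mu, G, \delta, \rho)$ with
$\lambda$ as a numerical surrogate for incompressibility.

The engineering moduli follow in closed form:

$$E_T = 3\mu + \mu\frac{\delta}{4\mu+\delta}, \qquad E_L = 3\mu + \delta,$$
$$\nu_{TT} = \tfrac12\!\left(1+\frac{\delta}{4\mu+\delta}\right),\quad
 \nu_{TL} = \tfrac12\!\left(1-\frac{\delta}{4\mu+\delta}\right),\quad
 \nu_{LT} = \tfrac12,$$

with the identities $\nu_{TT}+\nu_{TL}=1$, the isotropic limit $E = 3\mu$, and
the saturation $E_T \to 4\mu$ as $\delta \to \infty$. `engineering_moduli()`
implements the closed forms; `moduli_from_compliance()` inverts the full 6×6
stiffness and reads the same quantities from compliance entries, serving as an
independent numerical cross-check (they agree to $10^{-4}$ relative at
$\lambda/\mu = 10^8$).

### Choice of $\lambda$, $Q_1/Q_2$, and $\rho$

* $\lambda$ defaults to $10^5 \max(\mu, G, |\delta|)$. It is never fitted;
  doubling it changes derived moduli by under $10^{-4}$ relative, and
  the Rayleigh solver's results change by under $10^{-4}$ relative between
  $\lambda/\mu = 10^5$ and $10^6$ (asserted in tests). A single finite-$\lambda$
  solver covers all regimes rather than a separate exactly-incompressible
  formulation.
* The split of $\delta$ into $(Q_1, Q_2)$ is unidentifiable in the
  incompressible limit; the default $Q_1 = 0$, $Q_2 = \delta$ is a convention,
  overridable subject to $Q_2 - 2Q_1 = \delta$.
* $\rho$ defaults to 1000 kg/m³, the standard soft-tissue assumption; speeds
  scale as $\rho^{-1/2}$, so any alternative density rescales moduli
  quadratically.

## Wave propagation

**Bulk waves.** `christoffel_speeds()` solves the Christoffel eigenproblem
$\Gamma u = \rho c^2 u$ for propagation at angle $\vartheta$ from the fiber
axis. The branch polarized normal to the plane of propagation direction and
fiber axis is pure shear with the exact closed form
$c_S = \sqrt{(G\cos^2\vartheta + \mu\sin^2\vartheta)/\rho}$; in the
incompressible limit the in-plane quasi-shear branch is
$c_{qS} = \sqrt{(G\cos^2 2\vartheta + (\mu+\delta/4)\sin^2 2\vartheta)/\rho}$,
so at 45° it equals $\sqrt{(\mu+\delta/4)/\rho}$ independent of $G$. Both
closed forms are validated against the finite-$\lambda$ eigensolution to
$10^{-3}$ relative. Branches are labelled by polarization, not sort order, so
crossings at degenerate angles do not swap labels; round-off eigenvalues are
clipped at $-10^{-9}\lambda$.

**Surface waves.** `rayleigh_speed()` solves the surface-wave boundary problem
with the Stroh formalism: at trial speed $v$ the sextic eigenproblem in the
depth-wavenumber ratio $p$ is linearised into the standard 6×6 Stroh matrix,
the three partial waves with $\mathrm{Im}\,p > 0$ (decaying with depth) are
kept, and the real determinant of the Hermitian surface-impedance matrix
$Z = -iBA^{-1}$ is root-found in $v$. Its monotone decrease on the subsonic
interval (Barnett–Lothe) makes bracketing reliable: a coarse 64-point scan
locates the lowest-speed sign change, refined by Illinois false-position to
relative tolerance $10^{-8}$.

Numerical edge cases worth knowing about:

* Beyond the transonic limit the decaying-mode selection fails; for
  off-symmetry directions that limit can sit below the nominal bulk-speed
  bound. The scan treats such failures as a boundary and recurses into the
  last finite interval, because at strong tensile anisotropy the surface wave
  hugs (and in the limit $\delta/\mu \to \infty$ joins) the bulk shear
  branch.
* At $\vartheta = 0°$ and $90°$ the displacement component normal to the
  sagittal plane decouples; the solver restricts to the 2×2 sagittal problem
  there, so the decoupled bulk branch (which can be slower than the surface
  wave when $G < \mu$) cannot block the root. The same numeric path — no
  special-cased analytics — still reproduces the printed limits: at 90° the
  speed is $0.9553\sqrt{\mu/\rho}$ for every $G$ and $\delta$.

One physical caveat we verified quantitatively (against an independently
written reference implementation of the same boundary problem): the
"$c_R(45°)$ is independent of $G$" approximation holds only once $G$ clearly
dominates both $\mu$ and $\delta$. For $G \approx \mu$ the surface wave is
capped by the sagittal bulk shear speed
$\sqrt{(G+\mu)/2\rho} < c_{qS}(45°)$ and therefore must vary with $G$; the
spread over $G/\mu \in [1, 5]$ is ~10–20% at moderate $\delta/\mu$, shrinking
below 2% only for $G/\mu \gtrsim 2$ (small $\delta$) or $\gtrsim 3$. Similarly,
the approach $c_R \to c_S$ at large $\delta/\mu$ is bounded below by the 4.47%
deficit that the $0.9553$ constant fixes at $\vartheta = 90°$. The test suite
asserts the attainable versions of both properties.

The measured observable is a group velocity while the model curve is a phase
velocity; for off-symmetry directions in anisotropic media these can differ.
The inversion follows the acquisition convention of fitting the
phase-velocity curve, and this remains a documented approximation.

## Synthetic wavefields and group-velocity estimation

`simulate_wavefield()` emulates the acquisition geometry of an acoustic
micro-tapping OCE scan: 256 lateral positions at 54.7 µm, 512 frames at
46.5 kHz, a Gaussian-enveloped tone burst (centre 1.5 kHz, 4 kHz full −6 dB
bandwidth, matching the stated excitation band) propagating at a prescribed
speed, optional $1/\sqrt{x+x_0}$ cylindrical spreading, and seeded Gaussian
noise. It is a kinematic generator: it reproduces arrival-time structure,
amplitude decay and additive noise, but not elastodynamic effects
(diffraction, mode conversion, guided-wave dispersion, near-field radiation
patterns). Passing estimator tests on these fields therefore demonstrates
correctness of the arrival-picking and regression logic, not robustness to
every artefact of real tissue data.

`estimate_group_velocity()` picks an arrival time per position — analytic
signal envelope maximum with 3-point parabolic sub-sample refinement
(default), or peak cross-correlation lag against the first trace — and
returns the inverse slope of the least-squares line $t(x)$. Positions within
one pulse FWHM of the earliest arrival are excluded by default (near-source
contamination); the threshold is configurable and the exclusion rule is a
declared default, not inferred from any dataset. A fit with $R^2$ below 0.9
raises a warning rather than an error. `local_speed_map()` slides a
`kernel`-pixel window (stride fixed at 1) across each row, producing exactly
`n_x - kernel` estimates per row — the 100-position, 20-pixel, 80-estimate
arithmetic of scar mapping.

## Inversion

`fit_angle_scan()` fits $(\mu, G, \delta, \alpha)$ to an angle-resolved speed
scan by bounded Levenberg–Marquardt least squares, with the fiber orientation
$\alpha$ offsetting the scan frame from the material frame. Initialisation
uses only printed closed forms: $\alpha_0$ at the scan speed maximum,
$\mu_0 = \rho(c_{\min}/0.9553)^2$, $G_0 = \rho(c_{\max}/0.9553)^2$,
$\delta_0 = \mu_0$. Because the cost is 180°-periodic in $\alpha$, up to five
restarts jitter $\alpha_0$ by ±30°; a restart that already reproduces the
data to 0.01% of the mean speed short-circuits the rest. The forward model is
evaluated directly at the requested angles (at most 13 per residual call) —
the C++ solver is fast enough that a cached interpolation grid would cost
more than it saves and would add an avoidable interpolation error. Finite
$\delta \ge 0$ bounds encode the fast-axis assumption; a negative lower bound
switches to slow-axis mode with a warning. Jacobians are forward differences
with a $10^{-4}$-relative step (`epsfcn = 1e-8`), large enough to ride above
the $10^{-9}$-relative solver tolerance.

`loo_cv()` refits the scan $N$ times leaving one point out, warm-started at
the full-scan optimum, and reports per-parameter fold means (the reported
estimate) and standard deviations. Fold orientations are unwrapped to within
90° of the full fit before averaging, since $\alpha$ is an axis, not a
direction. Whether measured scans should be sd-weighted is unstated in the
protocol we emulate; the default is unweighted, with `sd_m_s` weighting
available.

Problem sizes used in the shipped tests: a 3×3×3 grid of
$(\mu, G/\mu, \delta/\mu)$ with orientations cycling through
$\{-60°, 10°, 45°\}$ for the noiseless round trip; 100 seeds of 3%
multiplicative speed noise for the Monte-Carlo recovery study (single
restart — the data-driven initialisation lands in the right basin on these
well-conditioned scans, and jittered restarts only add runtime); 25-seed
studies for the wavefield estimator. These sizes give stable medians while
keeping the default suite comfortably interactive.

## PS-OCT optic-axis estimation

A linear retarder with physical axis $\psi$ rotates Stokes vectors on the
Poincaré sphere about the equatorial axis $(\cos 2\psi, \sin 2\psi, 0)$.
`simulate_stokes_trajectory()` propagates circularly polarised input
(default $(0,0,1)$) through a stack of such retarders — a pure-retarder,
single-scattering model; diattenuation and depolarisation are deliberately
absent, matching the *apparent* axis quantity being estimated.
`estimate_axis_profile()` recovers $\psi(z)$ by sliding a 3-state window along
depth and fitting a plane through the centred states by SVD; the smallest
principal direction is the rotation axis, and
$\psi = \tfrac12\mathrm{atan2}(n_U, n_Q)$ folded into $(-90°, 90°]$.

Two conventions had to be fixed where the procedure we emulate leaves them
open. First, an unsigned plane normal leaves $\psi$ ambiguous by 90°; we
orient the normal so consecutive states advance right-handedly about it
(positive retardance), which resolves the ambiguity. Second, windows whose
states span an arc under 1° on the sphere are masked invalid — this
collinearity threshold stands in for the unspecified "color filter" that
removes non-birefringent surface tissue: with no retardance the trajectory
carries no axis information, and the masked fraction rises to one as
retardance vanishes (tested). With the default 3-state window the plane is
exact through the points; the scatter decomposition is kept so larger windows
work identically.

`depth_averaged_axis()` averages valid orientations with doubled-angle
circular statistics (so $\{85°, -85°\}$ averages to $90°$, not $0°$), and
`compare_axes()` returns the acute angle between two axis orientations — the
quantity used to compare the mechanical symmetry axis from the wave-speed fit
with the optical axis, which on shared-truth synthetic subjects agree to
within 2°.

## Synthetic subjects

`make_synthetic_subject()` ties the chain together: one ground truth
$(\mu, G, \delta, \alpha)$ generates 13 wavefields whose speeds are the
forward Rayleigh solution at the 13 scan angles, plus a Stokes volume whose
dermal axis equals $\alpha$ beneath a non-birefringent surface layer
(20 steps by default, emulating the weakly birefringent superficial layer
seen in real skin). Every random draw derives deterministically from one
master seed via recorded sub-seeds, so artifacts are reproducible
byte-for-byte. Defaults mirror the acquisition protocol: 13 angles, 46.5 kHz,
54.7 µm, 256×512 fields. The dermal retardance default (6°/step) gives
trajectories that arc far enough for stable plane fits without wrapping.

## Known limitations

* No viscoelasticity: speeds are frequency-independent by construction, and
  dispersive wavefields are out of scope.
* The half-space assumption ignores the finite dermis thickness; guided-wave
  corrections for thin layers over hypodermis are not modelled.
* Slow-axis materials ($\delta < 0$) are supported only through validation
  warnings and an opt-in fit mode; branch labelling near degeneracies has not
  been exercised for $G \ll \mu$ combined with large negative $\delta$.
* The group-vs-phase velocity identification noted above.
* The wavefield generator is kinematic; the PS-OCT model is a pure retarder.
  Both state exactly what the passing tests certify — see the module sections.
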