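---
title: "Modelling perivascular CSF flow and solute transport across the sleep cycle"
author: "perivasc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling perivascular CSF flow and solute transport across the sleep cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perivasc)
```

# The scientific problem

Perivascular spaces (PVS) — the annular, CSF-filled sleeves between a brain
vessel's lumen and the surrounding astrocytic endfoot tube — are major
highways for solute transport into and out of the brain. Vessel diameter is
not static: across the sleep cycle, penetrating arterioles show slow
vasomotion (very-low-frequency, 0.1–0.3 Hz, and low-frequency, 0.3–1 Hz
oscillations) that is largest in NREM and intermediate-state (IS) sleep, a
sustained dilation in REM sleep that shrinks the PVS, and a constriction
with PVS enlargement upon awakening and during microarousals. Because the
endfoot tube is far stiffer than the vessel wall, these diameter changes
translate directly into oscillations of the PVS cross-section area, which
pump CSF axially and enhance solute dispersion.

`perivasc` implements the full analysis chain from diameter dynamics to
predicted transport:

1. a **synthetic-data generator** for hypnograms, lumen/endfoot diameter
   traces, two-photon *x–t* linescan stacks and ECoG/EMG recordings;
2. **linescan extraction** of lumen and endfoot diameters and PVS width;
3. the **signal chain**: Savitzky–Golay smoothing, five-band Butterworth
   decomposition, oscillation-event statistics, quality control, rule-based
   sleep scoring, and episode aggregation into band summaries;
4. a **quasi-steady Stokes model** of oscillatory CSF flow in the deforming
   annulus;
5. an **advection–diffusion solver** for dispersion enhancement, solute
   influx fronts and cardiac-pulsation scenarios.

# The flow model

The PVS is an axisymmetric annulus of length $L = 600\,\mu m$ between a
moving inner (vessel) wall at $R_v(t)$ and a fixed outer (endfoot) wall at
$R_{ast}$. The free cross-section area follows the measured oscillation
law

$$A(t) = \langle A\rangle\left(1 + \tfrac{a}{2}\cos\tfrac{2\pi t}{p}\right) - A_{SMC},
\qquad A_{SMC} = \alpha\,\langle A\rangle_{baseline},$$

where $\langle A\rangle$ is the median PVS area, $a$ the median relative
peak-to-trough amplitude of the area oscillation, $p$ the median lumen
peak-to-peak period, and $A_{SMC}$ an incompressible obstructed area
(smooth muscle, fibroblasts, matrix) taken as a fraction
$\alpha \in \{0, 0.25, 0.5\}$ of the baseline (quiet wakefulness) area.
Because the obstructing material is dominated by the vessel wall, it is
lumped as a layer adjacent to the inner wall, so the fluid annulus runs
from $R_v(t) = \sqrt{R_{ast}^2 - A(t)/\pi}$ to $R_{ast}$.

At the study's scales the Womersley number is at most about 0.1 and the
Reynolds number about $3\times 10^{-3}$ (gap $h = 10\,\mu m$, frequency
15 Hz, velocity 200 μm/s, water viscosity at 35 °C,
$\mu = 0.693$ mPa·s), so inertia is negligible and the Stokes flow is
quasi-steady. With an axially uniform deformation, mass conservation fixes
the axial volume flux exactly:

$$Q(y, t) = \frac{dA}{dt}\,(L - y), \qquad \bar u(y,t) = Q/A,$$

with $p = 0$ at the surface entrance ($y=0$) and no flow at the deep end
($y=L$). The radial profile is the classical annular Poiseuille profile,
which yields the peak velocity (its pointwise maximum, attained at the
entrance) and, through the annular conductance
$k = \tfrac{\pi}{8\mu}\big[R_{ast}^4 - R_v^4 - (R_{ast}^2-R_v^2)^2/\ln(R_{ast}/R_v)\big]$,
the axial pressure gradient and end-to-end pressure difference. The
solution is analytic; `massConservationResidual()` confirms
$\partial_t A + \partial_y(A\bar u) = 0$ to machine precision, and the
conductance is verified against direct numerical integration of the
profile and, in the thin-gap limit, against the plane-Poiseuille $h^3$
law. A full moving-mesh discretisation is deliberately out of scope: at
$Wo \ll 1$ and $Re \ll 1$ the reduced solution *is* the Stokes solution up
to terms the package's property tests bound (linearity in the wall
velocity, $1/p$ scaling, obstruction monotonicity of the peak velocity).

# The transport model

Tracer concentration obeys advection–diffusion on the deforming annulus.
The solver (C++ core) uses

* the annular Poiseuille axial velocity $u = \bar u(y,t)\,\phi(r,t)$,
  normalised so the discrete area-weighted mean of $\phi$ is exactly 1;
* the **exact incompressible radial velocity**
  $r\,v(r) = R_v \dot R_v + (\dot A/A)\,S(r)$, with $S$ the cumulative
  area integral of $\phi$ — the velocity field is divergence-free and
  matches both wall velocities;
* a boundary-fitted radial mapping $r = R_v(t) + \eta\,(R_{ast}-R_v(t))$
  with mesh-relative face velocities, and a conservative finite-volume
  discretisation: with no-flux boundaries, total tracer mass is conserved
  to machine precision;
* Strang splitting per step: Crank–Nicolson radial diffusion/advection
  (tridiagonal per axial column; unconditionally stable, so tight
  obstructed gaps do not throttle the step) around an explicit Heun step
  for the axial terms.

The time step never exceeds $5\times10^{-3}$ s and is further limited by
the axial CFL conditions ($0.2\,\Delta y/u_{max}$ and
$0.2\,\Delta y^2/2D$) and by fifty steps per oscillation period; a
user-supplied step that violates these bounds is rejected. The axial
spacing is at most 1 μm and at least 8 radial cells span the gap (defaults:
$\Delta y = 1\,\mu m$, 10 radial cells).

A first-order implicit (backward Euler) integrator was considered and
rejected: its temporal truncation error acts as a numerical diffusivity of
order $u^2\Delta t/2$ — up to ~25 μm²/s at $u = 100$ μm/s and
$\Delta t = 5$ ms, larger than the molecular diffusivity of 70 kDa dextran
(17 μm²/s) — which would swamp the few-percent dispersion enhancements the
analysis is about. The Heun/Crank–Nicolson combination is second-order and
free of that artifact.

## Solutes

The registry (`knownSolutes()`) carries 70 kDa dextran at
$D = 17\,\mu m^2/s$ (apparent diffusion $0.84\times10^{-7}$ cm²/s in
neuropil, tortuosity 2) and 2000 kDa dextran. For the latter the
literature value printed alongside the 70 kDa one, $6.8\times10^{-7}$
cm²/s (68 μm²/s), *exceeds* the 70 kDa coefficient, which is physically
inverted for the larger molecule; both 68 and 6.8 μm²/s are therefore
selectable (`dex2000`, `dex2000_alt`) and neither is asserted as intended.

## Dispersion enhancement and the strain-phase correction

`dispersionEnhancement()` releases a Gaussian of s.d. $\sigma_0 = 2\,\mu m$
at mid-PVS, evolves it for $T = 40$ s, and fits the 1-D point-release
profile

$$c(y,t) = \frac{c_0}{\sqrt{4\pi D_{eff} t}}
\exp\!\left(-\frac{(y-L/2)^2}{4 D_{eff} t}\right),
\qquad c_0 = \sqrt{2\pi\sigma_0^2},$$

with the virtual origin $t_0 = \sigma_0^2/2D$, reporting the enhancement
$R = 100\,(D_{eff}-D)/D$. The fit is cross-checked against the moment
estimator $(\sigma^2(T)-\sigma^2(0))/2T$; a discrepancy above 2 % raises a
warning and the fit is reported.

One subtlety deserves emphasis. The oscillating annulus imposes a uniform
axial strain field ($\partial_y u = -\dot A/A$): the tracer cloud is
alternately stretched and compressed, so the *instantaneous* variance at a
fixed readout time is modulated by the exact kinematic factor
$\langle A^2\rangle / A(T)^2$. This is an $O(a)$ effect, while shear
(Taylor/Watson) dispersion is $O(a^2)$; reading the profile at an
arbitrary phase can therefore report spurious enhancements of either sign
— including negative ones — for weakly oscillating vessels. The package
measures at the nearest whole-cycle instant (where the wall velocity is
zero, the radial profile is homogenised and fit and moment estimators
agree) and multiplies by $A(T)^2/\langle A^2\rangle$, so the reported
$D_{eff}$ is the cycle-averaged effective diffusivity. With this
convention the enhancement is non-negative, scales with the amplitude
squared in the small-amplitude regime, and reduces to $D$ without flow —
properties the test suite asserts.

A consequence worth knowing: at fixed absolute area oscillation,
obstruction raises the mean velocity as $1/A$ but thins the gap roughly as
$h \approx A/2\pi R$, and quasi-steady shear dispersion scales as
$(u h)^2/D$ — an $\alpha$-invariant product to leading order. In this
reduced model the cycle-averaged enhancement is therefore nearly flat and
mildly *decreasing* in $\alpha$ at realistic amplitudes, even though peak
velocity, pressure gradient and influx speed all increase strongly with
$\alpha$. An apparent increase of the *fitted* enhancement with
obstruction can arise from the strain-phase artifact described above,
because the relative area excursion — and with it the phase modulation —
grows with $\alpha$; the package's phase-corrected estimator removes that
contribution by construction.

## Influx fronts and cardiac scenarios

`influxFront()` holds $c = 1$ at the surface entrance at all times
(including outflow phases — the resulting artificial source during
outflow is accepted as the model's convention), starts from $c = 0$, and
tracks the front — the deepest location where the section-averaged
concentration reaches 0.1, sub-cell interpolated. It returns the first
time the front reaches a target depth (censored, not an error, if it never
does) and a trajectory optionally time-smoothed by a centred moving
average spanning exactly one oscillation period. Under pure diffusion the
front time to 100 μm agrees with the semi-infinite closed form
$t = \big(x / 2\,\mathrm{erfc}^{-1}(0.1)\sqrt{D}\big)^2 \approx 109$ s.

Because cardiac-band PVS area oscillations are below the imaging
resolution, `cardiacScenario()` instead imposes the area amplitude that
makes the solved peak velocity hit a target (10, 50 or 100 μm/s) at a
cardiac period (default 0.1 s), by bracketed root finding to 1 %, and then
runs the transport analyses with the calibrated model.

# The signal chain

Diameter traces are smoothed with an order-3 Savitzky–Golay filter over a
0.1 s window (nearest odd sample count) and decomposed with zero-phase
(forward–backward) order-3 Butterworth filters into five bands: continuous
(0–0.1 Hz low-pass), VLF (0.1–0.3), LF (0.3–1), respiratory (1–4) and
cardiac (4–15 Hz). Zero-phase filtering is chosen so event times are not
lagged. Local extrema are detected with strict trough/peak alternation (of
two same-kind neighbours the more extreme survives); the peak-to-trough
(P–T) amplitude is the rise from a trough to the next peak and the P–P
period the time between consecutive peaks.

Episode aggregation follows a mean-then-median scheme: events are averaged
*within* each episode (a maximal single-state span, at least 10 s by
default), the P–T area amplitude is divided by the episode's median area
(making $\langle a_{P-T}\rangle$ dimensionless, which the area law
requires), and the *median across episodes* populates the per
(vessel, state, band) summary. Respiratory- and cardiac-band summaries of
endfoot-derived quantities are computed but flagged `reliable = FALSE`:
at the imaging resolution those amplitudes are not trustworthy.

Quality control rejects structures whose two edge-position series
correlate below 0.8 (lumen) or 0.7 (endfoot tube) — both edges share the
rigid tissue motion, so a weak correlation implies a tracking failure.
Constant series are an explicit failure ("undefined correlation").

## Sleep scoring

Scoring works on epoch-wise band powers of the 0.5–30 Hz ECoG (delta
0.5–4, theta 5–9, sigma 9–16 Hz) and the EMG: high EMG gives wake; low
EMG with theta/delta power ratio strictly above 0.5 gives REM; low EMG
with sigma rising (×1.8) and delta falling (×0.7) against a running
baseline of trailing NREM epochs gives IS; the remainder of low-EMG sleep
is NREM. Wake-like runs inside NREM/IS with an ECoG total-power drop
lasting at least 1 s but under 10 s are microarousals. Wake immediately
before NREM is relabelled WBS (15 s), wake after REM is WAS (10 s).

Numerical choices, all exposed as parameters: the epoch is 0.5 s (a 1 s
epoch dilutes a sub-second EMG burst enough to mis-score it as a
microarousal; half-second epochs give the ≥ 1 s rule a clean run-length
form); band powers are smoothed with a 5-epoch running median (short-epoch
power estimates are chi-squared noisy); REM and IS candidates shorter than
5 s and 1 s are returned to the surrounding slow-wave state; the EMG
high/low split is a deterministic two-means clustering of log epoch power
(overridable by an absolute threshold); a wake run of $n$ epochs is
compatible with true durations in $((n-2)\varepsilon, n\varepsilon)$, and
is accepted as a microarousal when that interval intersects [1, 10) s.

# The synthetic-data generator

The generator defines the study conditions for every test. Hypnograms
follow the canonical cycle WBS (15 s) → NREM (120 s) → IS (30 s) → REM
(60 s) → WAS (10 s), with microarousals inserted into NREM/IS as a Poisson
process (durations uniform in [1, 10) s, 1 s margins). Diameters are sums
of state-gated band-limited sinusoids — constant amplitude with one
uniform random phase per (episode, band), shared between lumen and endfoot
so the area oscillation is coherent — with exponential state-transition
ramps (τ = 2 s), independent Gaussian measurement noise per diameter
sample (0.05 μm), and a shared rigid drift on the centreline. The drift is
a mean-reverting random walk (stationary s.d. 3 μm, reversion 10 s)
rather than an unbounded walk, so a vessel stays inside a 40 μm field of
view for arbitrarily long recordings while still dominating the edge
correlation that the QC filter keys on.

Default per-state medians and amplitudes (`vesselParams()`) are plausible
placeholders for a penetrating arteriole — lumen 16 μm, endfoot 24 μm,
NREM VLF relative amplitude 0.10 at 0.2 Hz, LF 0.05 at 0.5 Hz, REM
dilation ×1.2 with PVS shrinkage, arousal constriction ×0.93 with PVS
enlargement, small respiratory/cardiac components — not measured values,
and every number is overridable. The endfoot oscillates at half the
lumen's relative amplitude, in phase.

Linescan stacks render the lumen as a dye-filled boxcar and the endfeet
as two flanking bands (outer edges one endfoot diameter apart), convolved
with a Gaussian PSF (s.d. 0.3 μm) and corrupted with additive noise;
ground truth is embedded. ECoG is a sum of band-limited noise components
with state-gated amplitudes (NREM delta-dominant; IS sigma-elevated,
delta-reduced; REM theta-dominant with theta/delta power well above 0.5);
EMG is amplitude-modulated broadband noise, lowest in REM.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: amplitude is constant within an episode
(real vasomotion waxes and wanes), oscillations are single carriers per
band rather than broadband, ECoG states are stationary within episodes,
no locomotion artefacts, no vessel branching or focal-plane drift, and
the deposited cohort's actual per-vessel distributions are deliberately
not matched.

# Degenerate inputs and tie-breaks

Downsampling factors minimise $|f/k - \mathrm{target}|$ over positive
integers with ties toward the smaller factor (250 Hz → 3, 333 Hz → 3
toward 100 Hz; the spatial factor targets 20 samples/μm). Frames with no
threshold crossing are flagged missing and excluded, never interpolated.
Negative PVS widths are retained but QC-flagged. A collapsing annulus
($\min_t A \le 0$ or $R_v \to 0$) is rejected at model construction.
States with no usable episode are absent from summaries, not zero-filled.
A front that never reaches the target depth is censored, not an error.

# Problem sizes used by the tests

The test suite runs the full 600 μm geometry for the acceptance checks
(pure-diffusion influx, amplitude scaling, obstruction sweep) and shorter
domains (300–400 μm) with 10 s horizons for the conservation and limit
properties; the Taylor–Aris verification uses a 1200 μm domain with a
steady 30 μm/s flow so the pulse stays clear of the boundaries. These
sizes were chosen so each property is measured in its asymptotic regime;
the solver accepts the full-scale settings unchanged.

# Known limitations

* The flow solution is the lubrication reduction of quasi-steady Stokes
  flow; it is exact for axially uniform deformation at $Wo, Re \ll 1$ but
  carries no axial pressure-wave propagation (no peristalsis) and no net
  (rectified) flow mechanism.
* The transport solver's velocity field freezes the annular Poiseuille
  *shape* at each instant; wall-normal advection is included exactly, but
  profile distortions of order $Wo^2$ are not.
* Enhancement-versus-obstruction behaviour is regime-dependent (see the
  dispersion section); conclusions about obstructed PVS transport should
  rest on the influx and velocity predictions, which are robust.
* The sleep scorer is tuned for the generator's statistical structure;
  real recordings will need the exposed thresholds revisited.
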