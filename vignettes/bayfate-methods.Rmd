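---
title: "Modelling PAH fate, transport and cancer risk in a semi-closed narrow bay"
author: "bayfate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling PAH fate, transport and cancer risk in a semi-closed narrow bay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Semi-closed narrow bays trap land-derived pollutants: the head of the bay is
far from the open boundary, tidal currents weaken along the channel, and the
water-exchange capacity drops accordingly. Polycyclic aromatic hydrocarbons
(PAHs) discharged near the head therefore linger, partition onto suspended
particles, settle into the sediment, and end up as a chronic exposure source
for aquaculture and for people. `bayfate` implements the full chain needed
to study this mechanism on an idealized bay: tidal hydrodynamics, multiphase
PAH fate and transport, model validation and calibration, and incremental
lifetime cancer risk (ILCR) mapping.

This vignette is the package's account of the science: the governing
equations, the parameters that matter and their defaults, what the synthetic
study conditions emulate (and do not), the numerical choices, and the known
limitations.

## 1. Hydrodynamics

The flow model solves the depth-averaged (2D) shallow-water equations on a
rectilinear Arakawa-C grid:

$$\frac{\partial \zeta}{\partial t}
 + \frac{\partial (H_{tot} U)}{\partial x}
 + \frac{\partial (H_{tot} V)}{\partial y} = 0$$

$$\frac{\partial U}{\partial t} + U U_x + V U_y - fV
 = -g\zeta_x - \frac{g U \sqrt{U^2+V^2}}{H_{tot}\,\psi^2}
 + \frac{\tau_x}{\rho_0 H_{tot}} + A_h \nabla^2 U$$

with the symmetric V-equation ($+fU$), where $\zeta$ is the free surface,
$H_{tot} = H + \zeta$ the total depth, $\psi$ the Chezy coefficient,
$\tau = C_D \rho_A W^2$ the wind stress and $A_h$ the horizontal eddy
viscosity. Time integration is alternating-direction implicit (ADI) in the
Leendertse style: an x-sweep treating $\zeta$ and $U$ implicitly (one
tridiagonal system per grid row, friction linearized implicitly), then a
y-sweep for $\zeta$ and $V$. Continuity is applied in flux form, so closed
basins conserve volume to rounding; a lake at rest is an exact discrete
steady state. The open boundary prescribes the water level as a harmonic
synthesis $\zeta_b(t) = \sum_k a_k \cos(\omega_k t - \phi_k)$ over the nine
supported constituents (M2, S2, N2, K2, K1, O1, P1, Q1, M1), optionally
ramped over a few hours to suppress start-up transients.

Numerical choices worth knowing:

* Momentum advection is explicit first-order upwind — robust and
  positivity-friendly at the resolutions used here; the scheme's numerical
  viscosity is negligible for the small-amplitude regimes we validate
  against.
* Friction uses the total depth floored at `min_depth` (default 0.1 m).
  There is no wetting/drying: the bay is 5–25 m deep everywhere.
* `cfl_limit()` reports the explicit barotropic Courant step
  $\min(dx,dy)/\sqrt{gH_{max}}$. The ADI scheme is stable above it (the
  default 300 s step exceeds it deliberately, as coastal ADI models
  routinely do), but `run_hydro()` warns because accuracy degrades with
  very long steps.
* The Coriolis parameter defaults to $2\Omega\sin(39.4^\circ)$; the
  mid-latitude bay the defaults emulate sits near 39–40° N.

The solver is verified against closed-form physics in the test suite: exact
lake-at-rest preservation, volume conservation to 1e-8 over 1000 steps, and
the frictionless co-oscillating standing wave, whose head amplification must
match $1/\cos(kL)$ within 5% on a one-cell-wide channel.

## 2. PAH fate and transport

The pollutant model tracks the congener sum (ΣPAHs, ng/L) in the water
column, the bed-sediment concentration (ng/g dry weight), and the
deposition flux. One transport step is operator-split:

1. **Advection** — conservative flux-form first-order upwind, using exactly
   the face water fluxes the hydrodynamic step just produced. This makes
   the tracer update discretely compatible with continuity: a uniform
   concentration stays uniform, total tracer mass in a closed basin is
   conserved to rounding, and the scheme is positivity-preserving at the
   operating Courant numbers.
2. **Horizontal turbulent diffusion** — explicit flux form with
   $\sigma_{tx}, \sigma_{ty}$ (default 10.1 m²/s each).
3. **Source injection** — point discharges in ng/s per cell.
4. **Kinetics**, explicit Euler with non-negativity clamps:
   * *Air–sea exchange* (two-film): the transfer velocity is
     $k_{vol} = \left[\frac{1}{k_l} + \frac{R_g T N_g}
     {P\,k_g\,e^{a_1 + a_2/T}}\right]^{-1}$, applied as the sink
     $k_{vol}(C - C_{equ})/H_{tot}$. The exponential is the dimensionless
     Henry coefficient with entropy/enthalpy temperature coefficients
     $a_1, a_2$.
   * *Degradation*: $R = K_0 + K_1 K_t C$ (zero- plus first-order).
   * *Deposition*: the particulate fraction settles at the Stokes velocity
     $V_0 = \omega\, g d_p^2 (\rho_T - \rho_0)/(18\,V_e\,\rho_0)$, scaled by
     the adsorbed mass fraction $\omega$; the flux feeds the bed mass
     balance and the cumulative deposition accounts.
   * *Sediment–water exchange*: the seepage velocity
     $v_p = \phi D_{sw} (C_{sed}^* - C_w)/L_{sw}$ is upwinded by sign —
     upward transport carries the (volumetric) bed concentration, downward
     transport the mobile (particulate + dissolved) share of the water
     concentration. Bed concentrations in ng/g are converted to ng/L with a
     bulk dry density $\rho_b$ (default 1.3 kg/L), and the exchanging bed
     layer is `L_sed` = 0.1 m thick.

Every kinetic term's applied increment is accumulated into an explicit mass
ledger (advective boundary net, sources, volatilized, degraded, net to
bed), and the suite requires the ledger to close against the water-column
inventory to 1e-6 in closed basins.

### Phase partition

The total concentration is split into fixed fractions (organics 30%,
organisms 15%, dissolved 10%, particulates 45%, summing to 1). Only the
particulate share settles; the dissolved+particulate share takes part in
bed uptake. The partition is static, not kinetic sorption — the fractions
are treated as constants of the system.

### Parameter defaults and why

| Parameter | Default | Meaning |
|---|---|---|
| $k_l$, $k_g$ | 4.15, 0.76 m/d | liquid/gas film transfer coefficients (calibrated values) |
| $a_1$, $a_2$ | 10.89, −4000 K | give a dimensionless Henry coefficient ≈ 0.05 at 15 °C, hence $k_{vol}\approx$ 0.04 m/d — the order reported for PAH air–water exchange; PAHs are semi-volatile, so volatilization must be a slow sink |
| $K_0$, $K_1$, $K_t$ | 0.003 ng/(L·d), 0.017 1/d, 1 | degradation constants |
| $\omega$, $d_p$, $\rho_T$ | 0.45, 5 µm, 1600 kg/m³ | adsorbed fraction and fine suspended-particle properties; $V_0 \approx 0.44$ m/d |
| $V_e$ | 1.5×10⁻⁶ m²/s | seawater kinematic viscosity (the calibration scans it on the conventional 10⁻⁶ scale) |
| $\phi$, $D_{sw}$, $L_{sw}$ | 0.45, 0.014 m²/d, 1 m | bed porosity, water–seabed diffusion, overlying layer |
| $C_{equ}$ | 5 ng/L | atmospheric-equilibrium dissolved concentration |

A note on the volatility coefficients: an early draft chose $a_1$ so that
the two film resistances were equal, which implies a Henry coefficient ~5 —
a volatile solvent, not a PAH mixture — and makes kinetic losses so fast
that the bay head reaches local equilibrium within days, the opposite of
the head-trap phenomenology this model exists to study. The shipped default
($H' \approx 0.05$) keeps volatilization a minor but calibratable sink and
leaves the head budget controlled by transport, which is the regime of
interest.

## 3. The synthetic study conditions

All real inputs (coastline, bathymetry, monitoring series) are replaced by
a synthetic module. The default bay is a 60 × 20 rectangular channel,
30 km × 6 km, 25 m deep at the mouth shoaling linearly to 5 m at the head,
with the single open boundary across the mouth. Forcing is mixed
semidiurnal/diurnal (M2 0.9 m, S2 0.3 m, K1 0.3 m, O1 0.25 m — amplitudes
chosen as typical of the semi-enclosed seas this class of bay sits in; the
harmonic constants are free inputs, not estimates). One shoreline source of
1.2×10⁸ ng/s ΣPAHs sits two cells from the head. The hot start sets 50 ng/L
inside the bay, 10 ng/L external water, and 5 ng/g in the bed. Stations sit
near the mouth (i = 4), mid-bay (i = 30) and near the head (i = 57) on the
channel axis.

Pseudo-observations add independent Gaussian noise to model series —
sufficient for exercising skill scoring and calibration, but deliberately
simpler than real observations (no drift, no gaps, no representation
error). Passing the validation and calibration tests therefore demonstrates
the machinery, not field accuracy: the rectilinear bay has no real
coastline, the congener mix is collapsed to a single tracked sum, and the
source strength is nominal, so absolute magnitudes (e.g. the annual bed
flux) are properties of the synthetic scenario only.

## 4. Validation, equilibrium detection, calibration

**Willmott skill.** Model/observation agreement is scored as
$\mathrm{Skill} = 1 - \sum|M_i - D_i|^2 / \sum(|M_i - \bar D| + |D_i -
\bar D|)^2$ with bands poor (≤ 0.2), medium (≤ 0.5), good (≤ 0.7),
excellent (> 0.7); boundary values fall in the lower band. Flow-direction
series are compared on the circle: deviations are angular distances and
$\bar D$ is the circular mean, so a 359° vs 1° disagreement counts as 2°.

**Dynamic equilibrium.** A station series is declared at equilibrium at the
first 1-day window boundary after which the window mean changes by less
than 1% (relatively) across 3 consecutive windows. The 1% threshold is the
package's definition of "fluctuating within a bounded envelope": a series
still drifting 2% per day is not at equilibrium. On the default 60-day run
the mouth station stabilizes around day 18 while the head station — fed by
the nearby source and ventilated weakly — takes until around day 26,
reproducing the mouth-fast/head-slow ordering that motivates the model.

**Calibration.** Five parameters are adjustable against observations, each
scanned on a bounded range with a fixed trial count — the defaults: Ψ
(Manning-type roughness 0.02–0.06, 48 trials; converted to the Chezy
coefficient as $C = H_{mean}^{1/6}/\Psi$, so Ψ = 0.035 ≈ C = 45 at 15 m),
$V_e$ (1.44–1.57 ×10⁻⁶ m²/s, 7), $k_g$ (0.73–0.78 m/d, 9), $k_l$
(4.12–4.19 m/d, 12) and $D_{sw}$ (0.012–0.015 m²/d, 3) — 79 forward runs
per pass. The algorithm is bounded coordinate descent: parameters are
scanned in a declared order (hydrodynamics first: Ψ, then $V_e$, $D_{sw}$,
$k_g$, $k_l$), each over evenly spaced values with the others held at their
incumbents, moving only on strict improvement (ties resolve to the lower
value). One pass is the default; the parameter-recovery experiment in the
acceptance suite uses two passes, because single-pass coordinate descent
lets an early-scanned sink parameter absorb the error of a not-yet-scanned
one. The default calibration station is the mid-bay station: it lies inside
the pollutant plume (so the kinetic parameters are observable in its
series) yet remains tidally dynamic (so the friction parameter is too);
the near-boundary mouth station is dominated by the clean inflow and is
nearly blind to the settling-viscosity parameter, and its skill saturates
to 1.0 in double precision near the optimum. The recovery objective is
minimum RMSE, whose dynamic range near a perfect fit is linear rather than
quadratic, avoiding that saturation.

## 5. Risk assessment

The bed-sediment ΣPAHs field is converted to a benzo(a)pyrene
toxic-equivalent (TEQ) concentration through a fixed congener composition
profile (uniform over the 16 priority congeners by default; the TEQ weight
is then the mean TEF, ≈ 0.152) and fed into the USEPA ILCR equations for
ingestion and dermal contact:

$$\mathrm{ILCR}_{ing} = \frac{C_S\, CSF_{ing}\,(BW/70)^{1/3}\, IR\, EF\,
ED}{BW\, AT\, 10^6},\qquad
\mathrm{ILCR}_{derm} = \frac{C_S\, CSF_{derm}\,(BW/70)^{1/3}\, SA\, AF\,
ABS\, EF\, ED}{BW\, AT\, 10^6}$$

with the standard exposure defaults (EF 350 d/y, ED 40 y, IR 100 mg/d, SA
5700 cm²/d, AF 0.07 mg/cm², ABS 0.13, AT 70×365 d, BW 70 kg, slope factors
7.3 and 3.85). Total risk is their sum, classified negligible (< 10⁻⁶),
potential ([10⁻⁶, 10⁻⁴]) or high (> 10⁻⁴). A particle-emission factor is
carried in the configuration for completeness but unused: no inhalation
pathway is modelled. On the default scenario the maximum ΣILCR (~1.4×10⁻⁶,
"potential") sits in the head third of the bay, next to the source — the
spatial risk pattern the model is built to expose.

## 6. Problem sizes and runtime

The shipped study conditions are sized for a desk machine: the 60 × 20 grid
at a 300 s step runs the 60-day coupled scenario in about two minutes, a
2-day calibration forward in about two seconds, and the 79-trial
calibration pass in a few minutes. The verification problems (standing-wave
channel, 300-cell Gaussian channel, 20 × 10 conservation basins) each run
in seconds. Scaling the grid or duration up is a matter of configuration,
at proportional cost.

## 7. Known limitations

* Rectilinear geometry only; no curvilinear metrics, no wetting/drying,
  no baroclinic (3D) dynamics.
* One tracked tracer (ΣPAHs): congener-resolved transport, kinetic
  sorption, sediment diagenesis and bioaccumulation are out of scope;
  speciation enters only through the TEQ composition profile.
* First-order upwind advection is diffusive at coarse resolution; the
  verification tests quantify exactly how much at the tested regimes.
* The bed module is a single well-mixed exchanging layer with a fixed bulk
  density; no consolidation or burial.
* Observation noise is Gaussian, independent in time — calibration and
  skill results on synthetic data are upper bounds on what field data
  would give.
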