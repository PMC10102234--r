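---
title: "From travelling clock waves to static somite boundaries: the psmsim model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From travelling clock waves to static somite boundaries: the psmsim model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(psmsim)
```

## The biological problem

During zebrafish somitogenesis the *her* genes oscillate in every
presomitic-mesoderm (PSM) cell; the oscillations form waves that travel
anteriorly and slow down, while somite boundaries appear one by one at
fixed positions in the embryo. `psmsim` implements a mechanistic account of
how the *dynamic* clock pattern becomes the *static* segmental pattern:
Ripply, induced once per clock cycle where the Her trough meets the
anterior edge of the Erk activity gradient, boosts degradation of Tbx6;
because Tbx6 sustains itself through a positive feedback loop (PFL), a
sufficiently strong Ripply pulse annihilates the high Tbx6 state through a
saddle-node (SN) bifurcation, and hysteresis keeps the cell low after
Ripply decays. The anterior border of the Tbx6 domain is therefore reset
once per cycle, six cells (one somite) posterior of the previous border,
and *her* expression arrests where Tbx6 is lost.

## The model

All concentrations are dimensionless (mRNAs scaled by the maximal *her*
transcription/decay ratio, proteins by the Tbx6 autoregulatory
production/decay ratio). Per cell $i$ at position $x_i$ in the tailbud
frame:

*her* mRNA (nascent $m_h$, mature $M_h$), with transcriptional delay
$\tau_h$ and splicing rate $\mu_{sh}$:

$$\frac{1}{\mu_1}\dot m_h =
 \frac{1}{1+(p_h(t-\tau_h)/K_1)^{n_1}}\, f(p_t(t-\tau_h)) - \mu_{sh} m_h,
 \qquad
 \frac{1}{\mu_1}\dot M_h = \mu_{sh} m_h - M_h$$

with $f(y) = (y/K_2)^{n_2}/(1+(y/K_2)^{n_2})$ for $x_i \le x_h$ (anterior:
Tbx6 required) and $f \equiv 1$ posterior of $x_h$ (other T-box factors
substitute in the tailbud).

*ripply* mRNA, repressed by Her and dpErk, activated by Tbx6 (delay
$\tau_r$):

$$\frac{1}{\mu_1}\dot m_r = \nu_1
 \frac{1}{1+(p_h/K_3)^{n_3}}
 \frac{1}{1+(p_e/K_4)^{n_4}}
 \frac{(p_t/K_5)^{n_5}}{1+(p_t/K_5)^{n_5}}\Big|_{t-\tau_r} - \mu_{sr} m_r,
 \qquad
 \frac{1}{\mu_1}\dot M_r = \mu_{sr} m_r - \mu_2 M_r$$

Proteins, with the position-dependent Her translational delay
$\tau_H(x) = \tau_{H0} + (\tau_{HL}-\tau_{H0})\,x/L$:

$$\frac{1}{\mu_3}\dot p_h = \nu_2 M_h(t-\tau_H(x_i)) - \mu_4 p_h,
 \qquad
 \frac{1}{\mu_3}\dot p_r = \nu_3 M_r(t-\tau_R) - \mu_5 p_r$$

Tbx6, the switch (no delays):

$$\frac{1}{\mu_3}\dot p_t =
 \underbrace{\frac{(p_t/K_6)^{n_6}}{1+(p_t/K_6)^{n_6}}}_{\text{PFL}}
 + \underbrace{\gamma\,
   \frac{1}{1+(F/K_{FR})^{n_R}}
   \frac{(F/K_{FA})^{n_A}}{1+(F/K_{FA})^{n_A}}}_{\text{IFFL}}
 - (1+\eta p_r)\,p_t$$

with the Fgf gradient $F(x) = F_0 e^{-(L-x)/x_f}$ static in the tailbud
frame. Because $K_{FA} < K_{FR}$, the incoherent feedforward loop (IFFL)
activates Tbx6 production only at intermediate signal levels — the mid PSM.
dpErk is a prescribed field, $p_e = 0$ anterior of the border $x_e(t)$ and
$\nu_e(1-e^{-q(x-x_e)})$ posterior of it; in `stepwise` mode the border is
lab-frame-static between resets ($x_e$ recedes at $u$ in the tailbud frame
from $x_E$, jumping back after travelling $\delta$).

Cells advect anteriorly at constant speed $u$; the cell reaching $x=0$ is
removed and a new posterior cell is appended at $x=L$, copying the
concentration variables *and the entire delay history* of its anterior
neighbour (the only choice that keeps the delayed terms well defined).
There is no Delta–Notch coupling: each cell is an autonomous delayed
oscillator, and cells are static in the lab frame
($x_{lab} = x_{tailbud} + u\,t$).

Steady states of the switch solve $P = D$ with $P$ the production curve
(PFL + IFFL) and $D = (1+\eta p_r)p_t$; for $n_6 = 2$ and no feedforward
offset, the nonzero roots solve $d\,p^2 - p + d\,K_6^2 = 0$ with
$d = 1+\eta p_r$, giving the closed-form SN threshold $d^\ast = 1/(2K_6)$
used as an independent oracle in the test suite.

## Parameters, units and calibration

Geometric and protocol values fixed by construction: $L = 400$ µm,
$\Delta x = 10$ µm ($N = 41$ cells), Euler step $dt = 0.01$ min, warm-up
460 min, delay ratio $\tau_{H0}/\tau_{HL} = 6$ (within the experimentally
motivated range $1\!-\!7$), stepwise-dpErk geometry $x_E = 200$,
$\delta = 60$, $x_e(0) = 180$ µm, and MEK inhibition as a ten-fold
reduction of $\nu_e$.

The remaining kinetic constants are the package's calibration, chosen once
to satisfy the wild-type behaviours the model must show and kept fixed:

* **Clock period.** $\mu_1 = 0.3$, $\mu_{sh} = 3$ (nascent *her* half-life
  under a minute, mature ~2.3 min), $\mu_3 = 0.25$, $\mu_4 = 1$ (Her
  half-life ~2.8 min), $\nu_2 = 2$, $K_1 = 0.1$, $n_1 = 2$,
  $\tau_h = 5.4$ min, $\tau_{HL} = 2.1$ min give a single-cell posterior
  period of 30.0 min — a zebrafish-like segmentation period. The advection
  speed is then *derived*: $u = 6\,\Delta x / T_{clock} = 2$ µm/min, so one
  clock cycle advects exactly one 6-cell somite. With the ratio 6,
  $\tau_{H0} = 12.6$ min and $\tau_H(x) = 7.45$ min at $x \approx 196$ µm —
  the anterior Tbx6 border region, which is where the single-cell
  bifurcation scan (`her_oscillation_scan`, default $\tau_H = 7.45$ min)
  operates.
* **Switch.** $K_6 = 0.4$, $n_6 = 2$: bistable with stable states 0 and
  0.8 at low signal and $d^\ast = 1.25$. $\gamma = 0.5$, $K_{FA} = 0.25$,
  $K_{FR} = 0.4$, $n_A = n_R = 4$ place the IFFL production window at
  $x \approx 205\!-\!355$ µm: newly added tailbud cells stay on the low
  branch, mid-PSM cells are driven to the high state, and anterior cells
  (where the IFFL offset falls below the lower fold, ~0.042) are bistable,
  which is what makes an eroded boundary permanent. Note the tailbud
  itself remains formally bistable — the PFL term is position-independent —
  with the low branch occupied; only the mid PSM is monostable-high.
* **Ripply pulse.** The pulse must hit the cells just anterior of the
  dpErk border hard, before they advect away: $\tau_r = 2$, $\tau_R = 1$
  min, fast turnover $\mu_2 = 2$, $\mu_5 = 2$ (Ripply protein half-life
  ~1.4 min, consistent with its experimentally rapid decay),
  $\nu_1 = 3$, $\nu_3 = 16$, and sharp gates $n_3 = n_4 = 4$
  ($K_3 = 0.2$, $K_4 = 0.15$) so Ripply is decisively on at the Her trough
  and decisively off under dpErk. $\eta = 3$ yields peak degradation
  factors of ~6–7, far above $d^\ast$. A sharp dpErk rise ($q = 0.2$/µm)
  confines protection to within about one cell of the border.
* $x_h = 250$ µm (not pinned by any measurement) places the
  Tbx6-requirement switch for *her* inside the Tbx6-high region; it is an
  ordinary configurable parameter.

Slower, softer variants of the Ripply arm produce qualitatively degraded
patterns (partial erosion, a creeping rather than ratcheting boundary);
the sharpened values above are the calibrated defaults precisely because
the wild-type invariants — one sharp persistent boundary per cycle, six
cells apart — demand them.

```{r defaults}
p <- default_parameters()
p
```

## Numerical scheme

* **Explicit Euler at $dt = 0.01$ min** is the reference integrator;
  higher-order schemes are deliberately out of scope to keep comparability
  with the scheme the model was formulated for. Halving $dt$ changes the
  wild-type Tbx6 field at $t = 60$ min by less than 0.05 (first-order
  behaviour, asserted in the tests).
* **Delays are exact.** Every delay is rounded to the nearest multiple of
  $dt$ (maximum error 0.005 min, ties away from zero), so each history
  lookup is an exact ring-buffer index — no interpolation. Histories are
  Lagrangian: they travel with cells, because the delays are per-cell
  biochemical lags. $\tau_H$ is evaluated at the cell's current position.
* **Advection as an index shift.** $dt$ is constrained to divide
  $\Delta x/u$, so advection is an exact one-index shift every
  $\Delta x/u = 5$ min; with all cells sharing one speed this is
  mathematically identical to continuous motion on the grid and avoids any
  resampling drift. Cell count is conserved exactly.
* **Negative excursions** (possible in principle with explicit Euler) are
  clamped to 0 and counted; anything below $-10^{-9}$ aborts with the cell
  and variable named. Default runs clamp nothing.
* **Initial history**: $m_h = M_h = 1$, $m_r = M_r = p_r = 0$,
  $p_h = \nu_2/\mu_4$ throughout the history window; $p_t = 1$ for
  $x \le x_h$, else 0; $p_e$ from its profile. The 460-min warm-up reaches
  the regular pattern; doubling it leaves the boundary statistics
  unchanged (asserted in the tests).
* **Two engines.** The production integrator is compiled (Rcpp); a pure-R
  stepper (`step_tissue`) performs the identical operations in the
  identical order and the suite asserts agreement at $10^{-12}$. This
  guards the compiled code against silent divergence from the documented
  update rule.
* **Root finding** (`find_steady_states`): sign-change scan (default
  $10^4$ points, doubled for verification, escalated automatically near
  tangencies) with `uniroot` refinement on $[0, 10(1+\gamma)]$ — the
  production bound guarantees all roots lie below. Stability is the sign
  of $d(P-D)/dp_t$; near-zero slopes are labelled `sn`, not stable. The SN
  threshold is found by bisection on the degradation factor to a relative
  $10^{-7}$.

## Scenario definitions

`her_ko` multiplies only the *her* transcription term by zero (splicing
and decay stay intact); `ripply_ko` sets $\nu_1 = 0$; `mek_inhibition`
divides $\nu_e$ by 10; `no_pfl` multiplies the autoregulation term by zero
(equivalent to $K_6 \to \infty$); `erk_stepwise` switches the border rule.
All scenarios return modified copies — parameter sets are never mutated.

## Pattern quantification

* **Boundary events** (`detect_tbx6_boundaries`): the instantaneous border
  is the anteriormost upward crossing of Tbx6 through the midpoint of the
  low and high stable states (computed from the parameters, not
  hard-coded). A formation event is a posterior jump of the lab-frame
  border by ≥ 2 cells between snapshots; its persistence is the time until
  the border recovers anterior of the formed position by more than one
  cell. Posterior progression (the next somite forming) does not end a
  boundary's tenure — under the ratchet kinematics the border is lab-static
  between events while the next boundary cell is being probed.
* **Somite spacing**: lab-frame distances between consecutive events, in
  cells.
* **Kymographs** in the tailbud frame are the recorded matrices; in the
  lab frame, columns are cells (exact inverse of the advection shifts, NA
  outside a cell's residence) and the transform round-trips losslessly.
* **Period profile** (`cell_period_profile`): because cells are
  lab-static autonomous oscillators, the period *gradient* lives on cells
  — at any fixed tailbud-frame position the pattern repeats with the
  single global (tailbud) period by phase conservation. Each cell's
  peak-to-peak intervals are therefore assigned to its tailbud-frame
  position at the interval midpoint. `measure_period_profile` is the
  per-column variant used on generic kymographs and fixtures.
* **Wave arrest** (`wave_arrest_position`): anteriormost position whose
  amplitude over the analysis window exceeds 20% of the posterior
  reference amplitude. Nascent *her* mRNA is the sharpest readout (it
  stops within a minute of Tbx6 loss); proteins blur the arrest front by a
  few cells through their decay times. There is no quantitative arrest
  criterion to inherit from experiment — the amplitude fraction is this
  package's definition, and it is configurable.
* **Domain extent** (`domain_extent`): support of a snapshot above a
  fraction of its maximum; used, e.g., to show the posterior extension of
  the *ripply* domain under MEK inhibition.

## The synthetic fixture generator

`generate_fixture` produces simulator-shaped data with exact ground truth:
static steps/sigmoids/boxcars, travelling waves
$A(x)(1+\sin 2\pi(t/T(x) - x/\lambda))/2$ with a programmed period
profile, and a sawtooth border that jumps posteriorly on schedule —
emulating step-like boundaries, anteriorly slowing waves, and periodic
boundary formation. Gaussian noise (clipped at zero) exercises detector
robustness. The fixtures validate the *detectors* independently of the
simulator; they do not emulate the nonlinear waveform shapes, the
amplitude envelope, or the erosion transients of the real model, so
passing fixture tests shows detector correctness, not model correctness —
the scenario tests cover the latter.

## Phase diagram semantics

`phase_diagram` varies the PFL strength ($K_6$) against the attainable
degradation boost (via the Ripply translation rate $\nu_3$), runs the full
tissue simulation per grid point, and classifies whether a persistent
boundary forms within one segmentation cycle — before the Ripply wave has
travelled one somite. The y-coordinate reported is the *achieved*
$1+\eta\,\max p_r$ near the dpErk border, measured from the run. The SN
curve is necessary but not sufficient: completing a six-cell boundary
within one cycle requires the degradation factor to clear the SN value
with a margin (about 1.3× at $K_6 = 0.4$ under the defaults), so the
formed/failed transition sits slightly above the SN curve — within one
cell of the log-spaced grid.

## Problem sizes used by the tests

The suite runs the full 41-cell tissue at $dt = 0.01$ min with the 460-min
warm-up and records 2–4 h of simulated development per scenario; the
steady-state oracle comparisons use 100 random parameter draws against a
$10^5$-point sign scan; the phase-diagram test uses a 2 × 6 grid. These
sizes were chosen to exercise at least four full segmentation cycles per
claim while keeping any single test in seconds.

## Known limitations

* One *her* and one *ripply* gene stand in for the duplicated zebrafish
  pairs; no Delta–Notch coupling, so cell-to-cell synchrony is inherited
  from the copied histories rather than maintained dynamically, and noise
  desynchronisation cannot be studied.
* dpErk is prescribed, not regulated; feedback from the clock onto Erk is
  out of scope.
* The default parameter set is a calibration that realises the documented
  qualitative behaviours, not a fit to measurements; no uncertainty
  quantification is attached to it.
* Explicit Euler is first-order; results are reported at the $dt$ the
  model was formulated with, and the convergence test bounds, but does not
  eliminate, the discretisation error.
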