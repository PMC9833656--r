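---
title: "A digital twin of a magnetically actuated tensile tester: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A digital twin of a magnetically actuated tensile tester: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tensiletwin)
```

## The instrument being twinned

The physical instrument stretches a millimeter-scale soft specimen (an
elastomer calibration sample or a strip of esophageal tissue) glued between
a fixed anchor and a ferromagnetic bead. An electromagnet pulls the bead; a
collimated light source casts the bead's shadow onto a 3648-pixel linear
CCD (8.0 µm pitch, 200 Hz, 8-bit ADC), which is the only position sensor.
There is no load cell: the tensile force is *computed* from the coil
current and the measured magnet-bead gap through a calibrated force law.
An embedded adaptive PID closes the loop at the frame rate.

`tensiletwin` reproduces this closed loop in software — actuator physics,
sample mechanics, sensor artifacts, controller — so that control design and
the downstream stress-strain analysis can be exercised, tested and
reproduced without hardware.

## Actuator model

The pull force on the proximal bead is

$$F_E(x, I, d) = F_0\, I^2 d^3 e^{-x/x_0},$$

with $F_0 = 6.13\times10^{6}\ \mathrm{N\,A^{-2}\,m^{-3}}$ and
$x_0 = 2.258\ \mathrm{mm}$, where $x$ is the gap from the magnet pole face
to the bead center. Force on the distal bead is orders of magnitude smaller
and modeled as exactly zero. `required_current()` inverts the law
analytically and flags (rather than throws on) saturation at `I_max`, so a
running control loop can clamp and continue, as the hardware driver does.

Two values the hardware documentation does not pin down are set here as
explicit configuration:

* **`I_max = 1 A`.** A ceiling exists in the driver but its value is not
  published.
* **Bead diameter `d = 6.35 mm`** (a standard 1/4-inch chrome-steel
  bearing ball, density 7850 kg m⁻³). The choice is driven by actuator
  authority: at the 8 mm working gap and `I_max`, the coil must deliver
  several times the peak spring force of the stiffest design-envelope
  sample (k = 20 N m⁻¹ stretched to 10% of an 8 mm gauge needs ≈ 16 mN);
  d = 6.35 mm provides ≈ 4× margin. This was fixed from the force-budget
  argument alone, before any closed-loop experiment, and not revisited.

## Sample and moving-body mechanics

The sample block is a Kelvin-Voigt element: restoring force
$k q + c\,\dot q$ in elongation coordinates $q = x_{\mathrm{start}} - x$.
For tissue, the elastic part may instead follow the strain-stiffening law

$$\sigma(\varepsilon) = \frac{E_0}{B}\left(e^{B\varepsilon}-1\right),$$

whose tangent modulus at zero strain is $E_0$ and which reduces exactly to
$E_0\varepsilon$ at $B = 0$. This functional form is this package's choice:
the tissue literature agrees the response is concave-up
("strain-stiffening") but no constitutive equation is printed for these
specimens; a single-exponential law is the simplest family that can match
a prescribed tangent modulus at a prescribed strain. A glued soft strip
cannot push, so compressive spring force is clamped at zero and flagged
("slack").

The moving body (two beads plus the 3D-printed buoyancy cell) is neutrally
buoyant, so gravity drops out; drag follows the chamber-calibrated linear
law $F_D(u) = 1.68\times10^{-3}\,u$, which at protocol speeds
(strain rates ≤ 0.1 s⁻¹ on mm gauges) stays below a few µN and is
negligible against spring forces. Default moving mass is two beads plus a
10 mg cell (≈ 2.1 g total); it is explicit configuration because no value
is published.

## Sensor model

`render_shadow()` area-samples the bead shadow onto the pixel grid: fully
shadowed pixels at `dark_level`, illuminated ones at `bright_level`, edge
pixels linearly interpolated by occluded fraction, then Gaussian read noise
(sd `noise_sd`, in ADU) and 8-bit quantization.

`locate_shadow()` mirrors a minimal firmware algorithm: classify pixels
against the mid-threshold, find the single dark run (wider than 2 px), and
recover each edge by *linearly inverting the occlusion fraction* of the two
pixels bracketing the transition; the estimate is the midpoint of the two
edges. The occlusion-fraction inversion is chosen over naive linear
interpolation between sample points because it is exact for area-sampled
edges: interpolation between pixel centers carries a deterministic
sub-pixel bias of up to ~0.09 px that the fraction inversion removes
entirely, while using the same threshold-and-edges structure. Plateau
levels come from the calibrated configuration, as in a calibrated
instrument.

Noise default: `noise_sd = 12` ADU, a realistic read-noise level for an
8-bit line CCD at 190 ADU contrast. The physical sensor's published
precision is 1.6 µm (0.2 px); we read that figure as a bound the instrument
meets, not a quantity to reproduce exactly — a Gaussian ADU noise large
enough to *produce* 0.2 px of localization scatter (~50 ADU) would also
defeat the run-detection stage that the same firmware uses. Under the
default the simulated static precision is ≈ 0.05 px, comfortably inside
the bound; the test suite asserts the bound, not the point value.

`delay_frames` defaults to 0: the firmware localizes a frame and executes
the controller step within the same frame period, so no whole-frame latency
accrues beyond the zero-order hold. The parameter exists for latency
studies.

## Controller

The plant linearized about an operating point $(\bar x, \bar I)$ is

$$m\ddot q + c_t\dot q + k_{\mathrm{eff}}\, q = K_I\,\delta I,\qquad
K_I = \frac{2\bar F}{\bar I},\qquad
k_{\mathrm{eff}} = \hat k - \frac{\bar F}{x_0},$$

the $-\bar F/x_0$ term being the destabilizing magnetic stiffness of the
exponential law in elongation coordinates (it can make
$k_{\mathrm{eff}} < 0$ at high force — the reason the loop must be closed at
all). Matching the closed-loop characteristic polynomial
$m s^3 + (c_t + K_I K_d)s^2 + (k_{\mathrm{eff}} + K_I K_p)s + K_I K_i$
to $m(s - p_1)(s - p_2)(s - \bar p_2)$ with design poles
$p_1 = -60$, $p_{2,3} = -6.5 \pm j$ gives

$$K_d = \frac{m a_2 - c_t}{K_I},\quad
  K_p = \frac{m a_1 - k_{\mathrm{eff}}}{K_I},\quad
  K_i = \frac{m a_0}{K_I},$$

with desired monic coefficients $(a_2, a_1, a_0) = (73,\ 823.25,\ 2595)$.
The gains are recomputed at every 200 Hz tick from the measured operating
point, so the *frozen-time* poles never move — the literal sense of
adaptive pole placement. `Ki` is ceilinged (`Ki_max`, default
5×10⁴ A m⁻¹ s⁻¹) and the integral term clamped and conditionally frozen
while the output saturates at 0 or `I_max` — the two printed wind-up
protections.

Implementation details that make the textbook design work in a sampled,
noisy, nonlinear loop (each is a configurable parameter with its default
stated; all were fixed from first principles or open-loop diagnostics, not
tuned against acceptance outcomes):

* **Derivative filtering** (`deriv_tau = 5 ms`, one frame). The derivative
  gain scales as $1/K_I$ and is large at low current; unfiltered
  backward-difference noise then chatters the command between 0 and
  saturation. One frame of first-order filtering bounds the amplification
  while adding only ~3° of phase at the fastest placed pole.
* **Operating-point floor** (`I_op_min = I_init = 0.02 A`). Below the
  floor, gains are computed as if the current were at the floor, keeping
  them bounded and continuous as the command approaches zero instead of
  flip-flopping between the bootstrap and adaptive gain sets. The modeled
  loop gain then exceeds the physical one, which errs toward gain margin.
  The initial bias current itself mirrors instrument practice (a low
  current is applied first to seat and align the specimen) and seeds the
  integral accumulator.
* **Reference-conditioned, filtered stiffness estimate.** The online
  secant estimate $\hat k = \bar F / q$ (clamped to [0, 100] N m⁻¹, zero
  before motion begins) is evaluated with the *commanded* elongation in
  the denominator, taking the measurement only when it exceeds the
  reference (overshoot), and is low-pass filtered with
  `k_hat_tau = 0.5 s`. Dividing by the fed-back measurement makes the
  estimate's sensitivity $\partial\hat k/\partial q \sim -\bar F/q^2$;
  multiplied by the steady ramp-following error this closes a parametric
  positive-feedback loop whose equivalent stiffness exceeds the physical
  spring severalfold near k = 20 N m⁻¹. We verified the mechanism
  directly: the frozen-gain sampled-data loop is stable by eigenvalue
  analysis at every operating point, the loop with the estimator disabled
  is stable in simulation, and the loop with the raw measured-denominator
  secant oscillates and diverges. Conditioning on the reference removes
  the feedback path (residual coupling of order error/reference ≪ 1)
  while preserving the estimator's contract.
* **Damping estimate `c_hat = 0`.** Sample damping is unknown to the real
  controller; assuming zero means the physical loop always has *more*
  damping than the design model, the conservative direction.

With these in place the closed loop is stable across the design envelope
(k from 0⁺ to 20 N m⁻¹, damping ratio 0 to 0.5, all three tissue strain
rates and the slow elastomer rate), which the test suite checks.

## Simulator

`run_closed_loop()` integrates bead + sample dynamics with fixed-substep
explicit RK4 — 10 substeps per 5 ms tick (0.5 ms steps; the fastest placed
pole has a 17 ms time constant, and the stiffest sample resonates at
~100 rad s⁻¹, both well resolved; a step-halving test asserts
convergence). Current is zero-order-held between ticks. The per-tick
sequence mirrors the firmware: render/localize the frame, update the
delay/drop bookkeeping, recompute gains, PID step, advance the plant. One
seed controls the sensor noise stream, and traces are reproducible
bit-for-bit under it. The inner loop is compiled (Rcpp) for speed; the
R-level module functions define the contracts, and consistency between the
two paths (noiseless measurements equal, gain snapshots equal, frozen-time
poles on spec) is asserted in the tests.

A run whose elongation exceeds 10 gauge lengths aborts with an instability
error carrying the trace prefix — the software analogue of the bead being
yanked into the magnet, which a sufficiently aggressive protocol on a stiff
specimen genuinely produces.

## Analysis chain

Engineering stress and strain are $\sigma = F/A$ and
$\varepsilon = (l - l_0)/l_0$. Matching the instrument, which has no load
cell, the force entering $\sigma$ is the coil force law evaluated at the
*measured* gap and current; drag is not subtracted by default (an optional
flag applies the correction). A useful consequence: the windowed Young's
modulus is insensitive to tracking lag, because stress and strain are both
functions of the same measured state — a constant-rate lag shifts points
*along* the stress-strain line, not off it.

`youngs_modulus()` fits an ordinary least-squares slope (with intercept)
inside a closed strain window; boundary points are included. A regression
rather than a two-point secant is used because the instrument's published
windows (5-10%, 0-10%, 50-60%) contain hundreds of samples and a
pre-tension offset must not bias the slope; on noiseless linear data the
two coincide.

`hysteresis_metrics()` integrates the loading/unloading stress difference
over the strain interval the two branches share, after interpolating both
onto a common grid. Integrating the raw closed polygon instead would count
the non-overlapping branch ends (which exist whenever the loop tracks with
lag) as spurious loop area. For a Kelvin-Voigt specimen under a triangular
strain protocol the loop area has the closed form
$2(c\,l_0/A)\,\dot\varepsilon\,\Delta\varepsilon$; the tests verify the
metric against it both analytically and through the full simulated
pipeline. One caveat the full pipeline makes visible: the measured loop
integral is $c\oint \dot q\,dq = c\int \dot q^2 dt$, so *any* velocity
ripple from the controller adds real, positive dissipation on top of the
ideal triangle value. At tissue rates the ripple is negligible; at the very
slow elastomer rate (2×10⁻³ s⁻¹, 6 µm s⁻¹) it is not, which is why the
quantitative loop-area check is run at a tissue rate while the elastomer
check asserts only that a purely elastic specimen shows a dissipation ratio
below 2%.

`preconditioning_deviation()` quantifies cycle-to-cycle stabilization as
the relative change of per-cycle maximum strain;
`preconditioning_converged_after()` reports the first cycle after which
all deviations stay below a threshold (default 5%).

## Fixtures: what the generator emulates, and what it does not

`make_fixture()` builds virtual specimens from the study's published
numbers:

* **Elastomers** `elite8` / `elite22`: linear, E = 216.0 / 541.8 kPa,
  capillary geometry d = 0.58 mm with l0 = 3.0 mm (chosen to keep the
  published >4:1 length-to-width ratio and to land `elite8` at
  k = E·A/l0 ≈ 19 N m⁻¹, inside the k ≤ 20 N m⁻¹ design window).
* **Tissue layers** (`esophagus_wall`, `epithelium`, `stroma`, `muscle`,
  `epi_stroma`): strain-stiffening laws with `E0 = E_P/3` and
  `B = ln(3)/ε_P`, so the tangent modulus at each layer's physiological
  strain ε_P equals its measured modulus E_P exactly while the small-strain
  tangent sits below it. The factor 3 encodes "visibly stiffening but
  single-exponential"; any factor > 1 satisfies the published constraints,
  and the downstream checks (tangent matching, composite consistency) are
  exact regardless of it.
* **Damping**: ratio 0.5 against the moving mass and small-strain
  stiffness, unless overridden (no specimen viscosities are published);
  `damping_ratio = 0` gives the purely elastic variants.

What passing tests on these fixtures do **not** show about real tissue:
the fixtures have no preconditioning memory (an ideal elastic or
Kelvin-Voigt specimen repeats its first cycle forever), no plasticity, no
anisotropy or layer-separation damage, and a one-parameter stiffening
shape. They exercise the instrument model and analysis chain, not tissue
constitutive realism.

## Multilayer composite model

For the layered esophageal wall the packaged table carries each layer's
thickness h, longitudinal residual strain ε_R (referenced to the cut-open,
layer-separated length, hence possibly negative), applied strain ε_S, and
modulus at physiological strain ε_P = ε_R + ε_S. The wall prediction uses
the iso-strain (parallel) rule of mixtures,

$$E_{\mathrm{wall}} = \frac{\sum_i h_i E_i}{\sum_i h_i},$$

adopted because layers glued side-by-side in a stretched wall share the
applied strain, and because it reproduces both published prediction rows
(two-layer and three-layer) within ~2%, inside their stated standard
deviations. The residual discrepancy plausibly reflects per-sample
averaging in the original analysis, whose exact semianalytical form is not
published. `composite_curve()` extends the same rule
to full curves, evaluating each layer's law at its residual-shifted strain;
when each layer's tangent at ε_P matches its E_P, the wall tangent at ε_S
reproduces the rule-of-mixtures modulus — an internal consistency check in
the tests.

## Problem sizes and tolerances

The test suite and acceptance script run: 15 validation ramps (3
stiffnesses × 5 seeds, 60 s of simulated time each at 200 Hz with 10 RK4
substeps), two elastomer recovery ramps, two triangle protocols, a handful
of short holds/cycles, a 1000-draw pole-placement sweep, and
400-replicate sensor Monte Carlo — a few seconds of wall time in total,
chosen as the smallest sizes at which the stochastic checks are stable to
their asserted tolerances. Numerical tolerances: pole placement to 1e-9 on
root locations; bisection for static equilibria to machine precision
(contract: |Δq| < 1e-12 m); RK4 step-halving agreement to 1e-4 relative;
windowed-modulus recovery to 5%; loop-area closed form to 2%.

## Known limitations

* Coil electrical dynamics (inductance, PWM driver transfer function) are
  treated as instantaneous; the published material does not include them.
* The full derivation of the plant model used on the embedded controller,
  and the exact form of the semianalytical composite model, are not
  published; the reconstructions here are declared as such and validated
  against every number the instrument's documentation reports.
* Published sensor "resolution" figures (106.0 / 115.0 µm) imply
  magnification factors that cannot be recovered from the text; they are
  represented only through the `magnification` parameter and are not
  asserted anywhere.
* Chamber thermals, CO₂/O₂ environment, and fluid-structure coupling
  beyond linear drag are out of scope.
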