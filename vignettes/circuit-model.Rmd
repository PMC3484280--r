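---
title: "An augmented Barlow–Levick circuit for motion onset and offset: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An augmented Barlow-Levick circuit for motion onset and offset: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blmotion)
```

## The scientific problem

Kinetic occlusion — one surface sliding behind another — produces local
discontinuities in the optic flow: patches of moving texture suddenly
appear (accretion) or stop and disappear (deletion). Detecting these
motion *onsets* and *offsets* is plausibly an early step of figure–ground
segregation. `blmotion` implements a one-dimensional rate model of this
computation: a Barlow–Levick nulling-inhibition motion detector whose
directional output feeds a second nulling stage tuned to sudden starts and
stops of motion, read out by slow evidence accumulators and mapped to
predicted manual reaction times.

## Circuit equations

All dynamic cells obey the shunting membrane equation

$$\tau \dot x = A(0 - x) + (\alpha - x)\,I_{\mathrm{exc}}
  - B(\omega + x)\,I_{\mathrm{inh}},$$

which confines activity to $[-\omega, \alpha]$; the rectified value
$[x]^+=\max(x,0)$ is the transmitted firing rate. Frozen drives give the
closed-form fixed point
$x^\* = (\alpha I_{\mathrm{exc}} - B\omega I_{\mathrm{inh}})
/(A + I_{\mathrm{exc}} + B I_{\mathrm{inh}})$, which the test suite uses
as an independent oracle for the integrator.

With positions $i = 1..7$, directions $d \in \{l, r\}$ (opposite $D$),
the layers are wired as follows (off-grid taps are zero):

| layer | excitation | inhibition |
|---|---|---|
| interneuron $x^{\mathrm{inh}}_{i,d}$ | input $I_i$ | $[x^{\mathrm{inh}}_{j,D}]^+$, $j$ one step ahead |
| directional $x^{\mathrm{dir}}_{i,d}$ | input $I_i$ | same tap as its interneuron |
| short-range filter $x^{\mathrm{srf}}_{i,d}$ | $10\,[x^{\mathrm{dir}}_{i,d}]^+[x^{\mathrm{dir}}_{k,d}]^+$, $k$ one step behind | — |
| onset $x^{\mathrm{on}}_{i,d}$ | $[x^{\mathrm{srf}}_{j,d}]^+$ ahead | $[x^{\mathrm{srf}}_{i,d}]^+$ own position |
| offset $x^{\mathrm{off}}_{i,d}$ | $[x^{\mathrm{srf}}_{k,d}]^+$ behind | $[x^{\mathrm{srf}}_{i,d}]^+$ own position |

"Ahead" means one step in the cell's preferred direction. Interneurons at
adjacent positions with opposite tuning inhibit each other, leaving a slow
decaying trace that substitutes for an explicit delay. The SRF product
nonlinearity silences the isolated, bidirectional transients produced at
stimulus appearance, so onset/offset cells only ever see *sequences* of
directional activity. An onset cell is vetoed when motion has already
passed through its own position (null sequence); an offset cell is
*pre-charged* by approaching motion and vetoed only if the motion
continues — this reversed temporal ordering is what differentiates offset
from onset behavior across speeds.

### Choice of the onset veto direction

For the onset cell's own-position inhibitory tap, a same-direction SRF
source ($x^{\mathrm{srf}}_{i,d}$) is the default: it mirrors the offset
equation and produces the null-sequence cancellation that keeps onset
cells silent during constant motion — with an opposite-direction tap the
veto would come from a practically silent cell and every position the
stimulus passes would fire an onset. The alternative remains selectable
(`onset_inh = "opposite"` in `simulate_circuit()`) for sensitivity
analysis.

## Parameters

Circuit constants (`shunting_params()`): $A = 0.1$ (passive decay; small,
so inputs produce large rate changes and inhibitory traces persist),
$B = 10$ (inhibition dominates excitation, enforcing a single signalled
direction), $\tau = 1$ (sets the simulation-time unit), $\alpha = 1$,
$\omega = 0.3$ (activity bounds; only their ratio matters), $C = 10$
(accumulator slowdown; the accumulator time constant is
$C\tau/A = 100$ time units). All are dimensionless except $\tau$.

## The stimulus and LGN front end

The stimulus is a single contrast patch occupying one position at a time:
position $i$ is active iff $\lfloor t v\rfloor = i - 2$ for
$i \in 2..6$ (half-open intervals: a switch instant belongs to the later
interval), so the input vanishes everywhere at $t = 5/v$. The occupied
position receives the constant drive $J(v)$, a magnocellular-LGN gain of
Benardete–Kaplan form:

$$J = F\sqrt{\Big(1 - \frac{2H_S - H_S^2}{1 + (\omega_t\tau_S)^2}\Big)
  \big(1 + (\omega_t\tau_L)^2\big)^{-N_L}},\qquad
  \tau_S = \frac{T_0}{1 + (c/C_{1/2})^2},\qquad
  \omega_t = 2\pi f_S v_{\deg},$$

with $H_S = 1$, $\tau_L = 1.68$ ms, $N_L = 25.5$, $C_{1/2} = 0.048$,
$f_S = 2.181$ cyc/deg, contrast $c = 0.1$, and normalizer $F = 2.206$.

The default $T_0 = 44.96$ ms is the value at which $F = 2.206$ normalizes
the curve exactly: the peak is then $J = 1.000$ at $6.84$ °/s, i.e. a
temporal frequency near 15 Hz, where magnocellular cells respond most
strongly. (With $T_0$ ten times smaller the same $F$ would cap the drive
at $0.133$ — too weak to drive the circuit through the 0.1 readout
threshold — and the peak would sit at an implausible temporal frequency;
the package therefore treats 44.96 ms as the operative constant.)
Contrast enters only through $\tau_S$ — the front end is strongly
contrast-gain-controlled — except that zero contrast means no patch and
hence zero drive.

Model speed $v$ (positions per time unit) converts to physical speed as
$v_{\deg} = w\,v$ with $w = 10$ °/s per model-speed unit, the same
constant used by the reaction-time transform; it is the single bridge
between the two unit systems.

## Readouts

Three accumulators integrate "correct" minus "incorrect" rectified
activity with slowdown $C$: onset (+ $x^{\mathrm{on}}_{2,r}$, −
$\sum_{i\neq2}x^{\mathrm{on}}_{i,r}$), direction
(+ $x^{\mathrm{dir}}_{6,r}$, − $x^{\mathrm{dir}}_{6,l}$), offset
(+ $x^{\mathrm{off}}_{7,r}$, − $\sum_{i\neq7}x^{\mathrm{off}}_{i,r}$).
Coupling is one-way; co-integrating them with the network and integrating
them afterwards against the recorded trajectory agree to better than
$10^{-5}$ (tested).

*Selectivity* is the peak rectified accumulator activity; *latency* is
the first crossing of threshold 0.1, referenced to motion onset ($t=0$)
for the onset accumulator and to the input-vanishing time ($5/v$) for the
offset accumulator. The direction accumulator has no natural event other
than motion onset, so its latency is referenced to $t = 0$ as well — the
only unambiguous choice, since directionality is established gradually.
Latencies that never cross are missing values, never sentinels. The
reaction-time transform is $\mathrm{RT} = c/s + r$ ($c = 100$ ms,
$r = 175$ ms); selectivities below $10^{-6}$ give missing RTs rather than
astronomical ones, since at such speeds undirectional pathways would
drive the response.

## Numerical choices

* **Integrator.** The drive is piecewise constant, so integration is
  restarted at every switch instant $m/v$ and the solver never crosses a
  discontinuity. Within segments the system is smooth and non-stiff;
  `lsoda` (default) and Dormand–Prince `ode45` agree to $2\times10^{-9}$
  on the canonical run, far inside the $10^{-5}$ integrator-independence
  bound asserted by the tests. `lsoda` is the default because the
  dense output grid (`dense_dt = 0.01 tau`, needed for reproducible
  sub-step latency interpolation) makes per-step solvers pay per sample.
  Tolerances: `rtol = 1e-8`, `atol = 1e-10`; halving them changes peak
  activities by less than $10^{-10}$.
* **Switch-instant roundoff.** $\lfloor t v\rfloor$ evaluated exactly at
  $t = m/v$ is floating-point fragile ($(m/v)\,v$ can round just below
  $m$), so each segment's constant drive is evaluated at the segment
  midpoint.
* **Horizon.** `t_end = 5/v + C*tau/A` by default, long enough for the
  slow accumulators to peak; `measure_run()` warns if an accumulator is
  still at its running maximum at `t_end`.
* **Peak LGN gain.** 400 log-spaced speeds on $[10^{-2}, 10^3]$ °/s
  followed by golden-section refinement (relative tolerance $10^{-8}$);
  the curve has a single interior peak.
* **Latency location.** Linear interpolation between the two dense
  samples bracketing the threshold crossing.

## Experiment sizes

The speed sweep uses 60 log-spaced model speeds on $[10^{-2}, 10^2]$
(physical $0.1$–$10^3$ °/s), covering the LGN-responsive band with wide
margins; the parameter sweep repeats it with $A$, $B$ or $\tau$ scaled by
$\{0.1, 1, 10\}$ — two orders of magnitude around the defaults. A single
unit-speed run integrates 73 states over 105 time units in about a
second; the full default sweep takes a few minutes, dominated by the
slowest speeds whose horizons reach 600 time units.

## What the simulations show — and do not show

With default parameters the sweep reproduces the qualitative physiology
and psychophysics the circuit was built to explain: onset/offset
selectivity far above directional selectivity in-band; offset latency
below onset latency, becoming *negative* (predictive) at low speeds;
reaction times decreasing with speed before an uptick at the band edge;
and offset reaction times slightly above onset reaction times at low
speeds, because "incorrect" offset activity during slow constant motion
erodes offset evidence.

One caveat is documented deliberately: onset selectivity exceeds offset
selectivity at *every* speed under the default parameters — the gap
shrinks monotonically from $7\times10^{-3}$ at the low band edge to zero
at high speed, so the relative high-speed boost of offset selectivity
appears as asymptotic convergence rather than a strict crossing. The
corresponding band-edge assertion in the acceptance tests is left
failing rather than weakened, since forcing a crossing would require
abandoning the standard parameter set.

The stimulus generator is idealized: a single noiseless patch, constant
speed, abrupt start and stop, one spatial dimension, and a space-time
separable front end. Passing tests therefore certify the circuit
mechanism — nulling inhibition, SRF gating, preemptive offset excitation,
accumulator readout — not robustness to stimulus variability, contrast
dynamics (the interneuron mutual inhibition is never exercised by
varying-contrast input here), two-dimensional kinetic contours, or
spiking realism. Those are explicit non-goals.

## Limitations

* The $w = 10$ °/s model-to-physical speed bridge is a modelling
  convention; changing it slides the selectivity curves along the speed
  axis relative to the LGN envelope.
* Accumulators are deterministic and non-competing; no trial-to-trial RT
  distributions.
* Grid edges are absorbing (phantom silent neighbors); the 7-position
  grid is the smallest that separates onset, constant-motion and offset
  events cleanly.
```{r example}
measure_run(v_model = 1)[, 1:8]
```
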