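---
title: "A lumped-parameter model of aspiration thrombectomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped-parameter model of aspiration thrombectomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clotbg)
```

## The problem

Most ischaemic strokes are caused by a blood clot occluding a cerebral
artery. Aspiration thrombectomy devices remove the clot without touching it:
a catheter is brought to within 2--3 mm of the proximal clot face and a
suction pressure is applied until the clot detaches from the wall and is
drawn into the device. Device development needs a clot model that is cheap
enough to couple to a device simulation --- not a CFD or FEA model --- and
that still captures the things that decide whether an extraction succeeds:
how strongly the clot adheres to the wall, how it detaches progressively
from the front, and whether it snaps before it is fully free.

`clotbg` implements such a model as a one-dimensional chain of lumped
elements, in the bond-graph idiom: partitions of the clot are inertias
(point masses), the connections between them are compliance--resistance
pairs (spring--dampers), and attachment to the wall is an effort source
that supplies whatever force keeps an attached partition still.

## The chain model

The axis runs along the artery, positive toward the device; partition 0 is
the proximal face. Positions are displacements from the initial
configuration, so the union springs start unstretched. For each *detached*
partition $i$ with mass $m_i$,

$$ m_i \ddot{x}_i \;=\; F_{\mathrm{app}}(t)\,[i = 0]
   \;+\; K_u (x_{i+1} - x_i) + R_u (\dot x_{i+1} - \dot x_i)
   \;-\; K_u (x_i - x_{i-1}) - R_u (\dot x_i - \dot x_{i-1})
   \;+\; F_{\mathrm{fric}}(\dot x_i), $$

with $K_u$ = 1.91 N/m and $R_u$ = 0.035 N·s/m by default (clot
stiffness measurements put $K_u$ at 3.41 ± 1.5 N/m; the default is the
lower edge of that interval and the parameter is exposed). An *attached*
partition has $\dot x_i = \ddot x_i = 0$ exactly: attachment is an
algebraic constraint, not a stiff spring. A very stiff anchor
(10^10 N/m, 10^9 N·s/m) makes the system needlessly stiff and its results
sensitive to the anchor constants, which is why the chain model abandons
it; it is retained only in the single-body model below, where those
constants are part of the model definition.

### Adhesion

Each partition is held by the platelet bonds of its wall-contact patch.
With platelet fraction $f_p$, mean platelet area $\mathrm{MPA}$ and contact
area $SA$, the patch carries $f_p \, SA / \mathrm{MPA}$ platelets, each
bonded to the wall with force $F_{\mathrm{platelet}}$, so

$$ F_{\mathrm{adh}} = \frac{f_p \, SA}{\mathrm{MPA}} \, F_{\mathrm{platelet}}. $$

For a cylindrical clot $SA = \pi D L / n$. With the reference values
($f_p = 0.96$, $\mathrm{MPA} = 5.31\cdot10^{-6}$ mm², $F_{\mathrm{platelet}}
= 32\cdot10^{-9}$ N, $D = 2.5$ mm, $L = 3$ cm, $n = 3$) each partition
adheres with 0.454 N. Total adhesion is invariant to the partition count
and linear in both $L$ and $f_p$; the test suite asserts both.

### Detachment and rupture

Detachment is event-driven and strictly front-to-back. The most proximal
still-attached partition releases when the pulling force transmitted to it
reaches its adhesion force: the applied aspiration force for partition 0,
and the union-*spring* tension $K_u (x_{j-1} - x_j)$ for an interior
partition $j$ (the printed release condition uses the spring force alone;
a `release_criterion = "net"` switch adds the damper term for users who
prefer the full transmitted force). Release permanently removes the
partition's adhesion and switches its wall friction to the dynamic law.
Events are located by the root-finding of `deSolve::lsodar` and the
integration is restarted after each one, so a release time is resolved to
solver precision rather than to the output grid.

If the spring tension of any union exceeds a finite rupture force
`F_rupture`, the simulation stops and flags the junction: a long clot can
accumulate more adhesion than its body can transmit, and snaps before it
is free. The check is off (`Inf`) by default.

### Friction

Wall friction is linear Stokes-type drag at rest, $-R_s v$ with
$R_s = 2.5\cdot10^{-6}$ N·s/m, dropping by one decade
($R_d = R_s/10$) when motion begins. The chain model defaults instead to
the quadratic Stokes law for a blunt cylinder,

$$ F_{\mathrm{dyn}} = -\operatorname{sign}(v)\,\frac{C}{8}\rho\,\pi D^2 v^2, $$

with $\rho$ = 1060 kg/m³ and form coefficient $C = 1.2$ (a typical blunt
cylinder value; no reference value is stated for $C$, so it is explicit in
the configuration). The quadratic law is linearized below
$|v| = 10^{-9}$ m/s so the vector field is smooth at the origin; the two
branches agree at the regularization boundary and the width is
configurable.

## The single-body model

The simpler variant treats the clot as one rigid body and asks only *when*
it starts to move. The wall binds it by surface tension $\gamma = F/l$
acting on the contact circumference $l = \pi D$, which doubles as the
spring constant $K = \gamma$ of a force-measurement spring. One anchor
sphere per 0.1 mm of clot (100 for 1 cm, 500 for 5 cm) gives the
equivalent measurement spring $K_{eq} = K/n$ --- the model's printed
combination rule, kept as the default even though parallel springs
conventionally add ($K n$ is available via `eq_spring_mode =
"parallel_sum"`). The body is pinned by the stiff wall anchor until the
measurement spring has stretched $x = F_{\mathrm{thr}}/K_{eq}$, which
happens exactly when the applied force reaches the movement threshold
$F_{\mathrm{thr}} = 0.01$ N; the anchor is then removed, friction switches
to dynamic, and the body accelerates. Note that with the printed $K/n$
rule the release displacement is decimetre-scale (0.785 m for the 1 cm
clot) --- the gate is consistent because the threshold is expressed in
force, but the displacement itself should not be read physically.

## Cardiac forcing

Arterial pressure over one 1 s cycle is approximated piecewise by two
polynomials in kPa (systole on 0--0.32 s, diastole on 0.32--1.00 s),
spanning roughly 11--16 kPa (80--120 mmHg). The pieces agree within
0.05 kPa at the switch and within 0.12 kPa across the periodic closure.
The model does not state on which surface this pressure acts; `clotbg`
applies it to the proximal cross-section, the same surface as the
aspiration, and by default as a *modulation* --- the waveform minus its
analytic cycle mean (13.11 kPa) --- so that enabling the heartbeat changes
the load fluctuation but not its mean. An `"absolute"` mode applies the
raw waveform instead.

```{r waveform}
range(cardiac_pressure(seq(0, 1, by = 1e-3)))
cardiac_cycle_mean()
```

## Stenosed arteries

An atheroma narrows the lumen; a clot formed there is moulded to it. The
lumen radius is modelled as a cosine bump over the clot extent,
$r(x) = R\,(1 - a\,(1+\cos(2\pi(x - L/2)/L))/2)$ with radial severity $a$
(no profile shape is prescribed by the reference geometry, which only
shows a symmetric narrowing; the severity of the packaged fixture is 0.5).
Partition cut points are chosen so every partition has the same
wall-contact area $\int 2\pi r\,\mathrm{d}x$, by inverting the cumulative
integral on a dense grid (20 000 intervals; the suite checks the cuts
against an independent 10^5-point cumulative-sum oracle to 10^-6
relative). Equal areas and equal volumes cannot generally both hold for
the same cuts; area wins because adhesion is area-driven, and the volume
spread is reported as a warning. Masses are `total_mass / n`. When the
clot has slid, `repartition_after_motion()` re-integrates the areas over
the shifted spans; in the chain simulation attached partitions have not
moved, so this only matters once partitions are already free (and
adhesion-less), but the operation is exposed for quasi-static analyses.

## Scenario conditions and defaults

All computation is in SI; configuration files carry explicit unit tags
because the source literature mixes mm, cm, g, mmHg and kPa. Choices the
reference parameter set leaves open are fixed once:

* **Clot mass** is an independent input, because density times the stated
  geometry does not reproduce the reported 0.5--2.0 g range. Fixtures use
  $m(L) = 0.5\,\mathrm{g} + 0.375\,\mathrm{g/cm}\,(L - 1\,\mathrm{cm})$,
  spanning exactly that range over 1--5 cm.
* **Aspiration programme**: suction increasing over the first second,
  implemented as a linear ramp 0 → −200 kPa over 1 s, then hold. −200 kPa
  exceeds the worst-case proximal adhesion (0.757 N over the 4.91 mm²
  cross-section ≈ 154 kPa, for the 5 cm, $f_p = 0.96$ clot), so every
  fixture detaches. Constant and tabulated programmes are also available.
* **Extraction distance** defaults to 2.5 mm, the midpoint of the 2--3 mm
  standoff maintained between device and clot.
* **Partition count**: 3 for plain fixtures, 5 for the stenosed one,
  matching the reference partitionings.

## What "extraction time" means

`extraction_time()` reports the first time the clot has covered the
extraction distance, interpolated linearly between output samples. Two
readings are offered. `"proximal_face"` (the default) tracks partition 0
--- the face the suction acts on. Because the proximal partition covers
2.5 mm within milliseconds of its own release, this reading is dominated
by the release time of partition 0 and is nearly independent of the chain
stiffness. `"whole_clot"` requires *every* partition (in particular the
distal end) to have covered the distance, i.e. the clot as a whole has
been pulled clear; this is the reading under which the qualitative claims
about removal hold and the one used for the stiffness property below.

Three monotonicity properties characterize the model, all asserted by the
test suite:

* stronger suction never slows extraction (5-level sweep, 3 cm clot);
* longer clots never extract faster at fixed suction (more adhesion, more
  mass);
* stiffer clots ($K_u$ ∈ {1.91, 3.41, 4.91} N/m) never extract slower in
  the whole-clot reading: a stiffer union reaches the next partition's
  release tension at a smaller stretch, so the detachment cascade runs
  faster. In the proximal-face reading this effect is invisible (the front
  partition's own release does not involve $K_u$) and the residual effect
  of the union spring braking the front partition makes stiffness very
  slightly *slow* that reading --- which is why the stiffness property is
  stated for whole-clot removal.

```{r extraction, cache = FALSE}
fx <- fixture_scenarios()
res <- simulate(fx$table1_L3cm, t_end = 1, dt = 1e-3)
res
extraction_time(res, mode = "whole_clot")
```

## Numerical choices

* Integration: `deSolve::lsodar` (automatic stiff/non-stiff switching with
  root finding), tolerances `rtol = 1e-8`, `atol = 1e-12` by default.
  Attached partitions are carried in the state with zero derivatives, so
  the rest invariant is exact (velocities identically zero, not small).
* Event handling: one root function for the next release (the force excess
  on the most proximal attached partition) and one for rupture. After a
  located root the release is applied even if the trigger is a rounding
  error below threshold, and releases cascade at a segment start if
  several triggers are already exceeded.
* Output: fixed grid (1 kHz by default) plus the exact event times. Runs
  are fully deterministic; reruns produce bit-identical CSV.
* Sweeps: `pressure_sweep()` classifies each level by whether extraction
  completes, then bisects between the strongest failing and weakest
  succeeding suction to 1% of the bracket. `minimum_release_force()` does
  the same over constant forces; on the single-body model it recovers the
  0.01 N threshold to the bisection tolerance.
* The problem sizes used by the tests (1--3 s windows, 0.1--1 ms output
  grids, 10^5-point oracles) resolve every event time to well below the
  asserted tolerances while keeping the full suite in tens of seconds.

## Limitations

* The chain is 1-D: no vessel compliance, no flow field, no 2-D/3-D
  platelet lattice. Detached partitions may interpenetrate attached ones
  (no contact mechanics); positions of long-detached partitions are not
  meaningful beyond "clear of the wall", and with the soft default $K_u$
  the inter-partition stretches at release are decimetre-scale.
* Re-adhesion does not occur, and rupture is a stop-and-flag, not a
  fragmentation model.
* The synthetic scenarios emulate the reference parameter set, not any
  patient data: passing tests show the implementation honours the model's
  stated laws and qualitative behaviour, not that the model predicts
  clinical extraction times.
* Quantitative extraction-time results in the source literature are
  graphical only, so the package validates against printed anchor numbers
  (anchor counts, waveform band, movement threshold) and properties, not
  against digitized curves.
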