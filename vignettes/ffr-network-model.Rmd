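---
title: "A lumped coronary network model for noninvasive FFR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped coronary network model for noninvasive FFR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffrnet)
```

## The problem

Fractional flow reserve (FFR) is the ratio of the mean pressure distal to
a coronary stenosis to the aortic pressure under maximal (adenosine)
hyperemia; values at or below 0.8 indicate hemodynamically significant
ischemia. Measuring it requires a pressure wire. `ffrnet` estimates FFR
noninvasively from a geometric description of the coronary tree plus a
handful of clinical scalars, by solving a steady, lumped (zero-dimensional)
resistive network whose outlet boundary conditions are identified from the
patient's own resting physiology.

The package's core is the boundary-condition identification chain:

1. **Resting flow.** Mean blood pressure is the cuff estimate
   $P_\mathrm{MBP} = (P_\mathrm{sys} + 2P_\mathrm{dia})/3$; total resting
   coronary flow is 4% of cardiac output.
2. **Allometric distribution.** At every junction, daughter flows scale
   with diameter as $Q \propto D^{7/3}$, normalized so flow is conserved.
   This is the form-follows-function scaling of coronary trees; shares are
   computed on healthy diameters because lesions live in the epicardial
   conduit, not in the distribution law.
3. **Epicardial resistance.** Each branch is a Poiseuille resistor
   $R = 8\pi\mu L / A^2$ with $A$ the mean of the end cross-sections;
   branches with diameter profiles (including stenosis overrides) are
   integrated piecewise, which reduces exactly to the two-point form for
   flat profiles.
4. **Microcirculation calibration.** Walking each root-to-outlet path
   proximal to distal, Ohm drops $\Delta P = R\,Q$ are subtracted from
   $P_\mathrm{MBP}$; the remaining outlet pressure over the outlet's
   resting flow is that outlet's resting microcirculatory resistance
   $R_i = P_i / Q_i$ (venous pressure taken as 0). Calibration is exactly
   the inverse of the resting network solve, which the test suite verifies
   to 1e-10.
5. **Hyperemia.** Inlet pressure is reduced by 12%
   ($P_0 = 0.88\,P_\mathrm{MBP}$) and microcirculation resistance scaled
   to 0.23 of rest, the accepted clinical statistics for adenosine;
   stenosis severity does not alter minimal microvascular resistance.
6. **Coupled identification.** Hyperemic outlet flows solve the coupled
   system "path drops + microcirculation demand = inlet pressure" per
   outlet. They are found by under-relaxed fixed-point iteration
   $Q_j \leftarrow (1-\alpha)Q_j + \alpha P_j / R_j$, with outlet
   pressures $P_j$ re-evaluated through the forward network solve after
   each update, until
   $\max_j |P_j - Q_j R_j| / P_0 \le 10^{-4}$.
7. **FFR.** $\mathrm{FFR} = P_d / P_0$ read 3 cm downstream of the
   lesion's distal shoulder (clamped, and flagged, at the branch end).

For the linear lesion model the coupled system is exactly linear, and
`direct_solve_linear()` provides an independent oracle
($(M + \mathrm{diag}\,R_j)\,Q = P_0\mathbf{1}$, $M_{jk}$ the shared-path
resistance); the iteration is tested against it on 100 randomized trees.

## A worked example

```{r}
tree <- load_tree(system.file("extdata", "demo-tree.json",
                              package = "ffrnet"))
tree
phys <- patient_physiology(p_sp = 126, p_dp = 80, cardiac_output = 4.2,
                           heart_rate = 68, myocardial_mass = 142.5)
res <- ffr_u(tree, phys)
res[, c("segment", "severity", "ffr", "p_d", "p_a", "converged")]
attr(res, "report")$iterations
```

The comparator `ffr_d()` distributes a fixed empirical hyperemic flow by
the same diameter law and performs a single pressure pass — it omits the
stenosis–flow coupling, which is exactly what `ffr_u()` adds:

```{r}
ffr_d(tree, phys)$ffr
```

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| flow fraction | 0.04 | – | resting coronary share of cardiac output |
| flow exponent | 7/3 | – | allometric diameter power |
| hyperemia pressure drop | 0.12 | – | inlet $P_0 = 0.88 P_\mathrm{MBP}$ |
| hyperemia resistance factor | 0.23 | – | $R_j = 0.23 R_i$ |
| viscosity $\mu$ | 0.0035 | Pa s | Poiseuille resistance |
| density $\rho$ | 1050 | kg/m³ | nonlinear lesion loss only |
| $\alpha$ | 0.3 | – | under-relaxation factor |
| residual tolerance | 1e-4 | – | normalized outlet mismatch |
| measurement distance | 0.03 | m | clinical 3 cm convention |
| $K_t$ | 1.52 | – | expansion-loss coefficient (optional) |

The four clinical coefficients are empirical statistics, not physical
constants, hence configurable through `ffr_config()`. In the limit of
negligible epicardial resistance the hyperemic/resting total-flow ratio is
$0.88/0.23 \approx 3.826$ exactly — a closed form the tests pin down.

## Design choices where the design was open

**Pressure update.** A literal damped update of the outlet pressures of
the form $P \leftarrow P + \alpha(P_0 - P + Q R_j)$ has the stationary
point $P = P_0 + Q R_j$, which contradicts both the flow update's fixed
point ($P = Q R_j$) and the matching condition that defines convergence.
We therefore re-evaluate outlet pressures through the network solve each
iteration, which enforces the matching condition by construction. The
literal variant is preserved behind `solver_settings(literal_relaxation = TRUE)`
for comparison; a test demonstrates that it drifts away from the true
solution (its residual tends to $1/(2-\alpha)$, never to zero).

**Relaxation-factor adaptation.** The damped iteration converges for
$\alpha < 2/(1+\lambda_{\max})$, where $\lambda_{\max}$ is the largest
eigenvalue of $R_j^{-1} M$; severe proximal stenoses push
$\lambda_{\max}$ well above the default's stability range, producing
period-2 residual oscillation rather than monotone growth. Counting
consecutive residual increases therefore never triggers; instead the
solver halves $\alpha$ and restarts from the best iterate whenever the
residual exceeds 4x the best seen **or** fails to improve for 20
iterations. With this rule every randomized test problem converges, at
worst in about 1100 iterations.

**Residual normalization.** The convergence quantity is dimensionless:
worst-outlet pressure mismatch divided by the inlet pressure, matching the
pure-number tolerance 1e-4.

**Initialization.** Default is the resting assignment (positive and close
to the solution). The alternative `"series"` start uses the decoupled
per-outlet Ohm estimate $P_0/(R_j + \sum_\mathrm{path} R_s)$; a literally
uniform split was rejected because no total-flow scale exists before the
solve.

**Measurement convention.** "3 cm downstream" is centerline arc length
from the lesion's distal shoulder, staying on the same branch; if the
branch ends sooner the most distal point is used and the result flagged
(`at_branch_end`). The denominator of FFR_U is the hyperemic inlet
pressure $P_0$, since the ratio is formed inside the simulated hyperemic
field.

**Negative intermediate flows** (possible under severe lesions at large
$\alpha$) are clipped to a small positive value with a warning; outlet
iteration order is sorted, so runs are bit-reproducible.

**Lesion pressure-loss model.** The default is piecewise-Poiseuille over
the stenosis-modified diameter profile, keeping the network linear and the
direct oracle exact. An optional expansion-loss term
$\Delta P_t = K_t \rho/(2A_0^2)\,(A_0/A_s - 1)^2\,Q^2$ with $K_t = 1.52$
models the extra three-dimensional head loss at the lesion exit that a
line model cannot see; it is off by default and documents the main gap
between this reduced-order model and a meshed 3D solve.

**Diameter at a junction.** The allometric law needs an "effective
diameter" per daughter; the package uses the proximal (junction-local)
diameter by default, with mean-of-ends as a configuration, since the
definition is not standardized.

**FFR_D total flow.** The comparator's empirical total-flow formula is
configurable and defaults to a documented stand-in,
$Q_\mathrm{rest} = k\,M^{0.75}$ with $k = 4.07$ mL/min/g$^{0.75}$
(calibrated so a 142.5 g myocardium receives 4% of a 4.2 L/min cardiac
output at rest), scaled by the hyperemic gain $0.88/0.23$. The choice is
echoed in the result metadata. Its inlet/denominator pressure is the mean
aortic pressure by default, with a diastolic option.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` draws binary trees whose junctions satisfy a
Murray-type relation $D_p^3 = D_1^3 + D_2^3$ with random asymmetry,
lengths proportional to diameter (ratio 10), a 10% within-segment taper,
and a 1 mm minimum branch diameter — the practical reconstruction limit of
clinical CT angiography. Physiology scalars match a stable-angina cohort
(cardiac output 4.2 ± 1.6 L/min, heart rate 68 ± 24 bpm, myocardial mass
142.5 ± 46.6 g, mean pressure near 95 mmHg). Each vessel carries one
stenosis with severity uniform on (0.2, 0.8), and the "invasive" reference
is the exact linear-network FFR plus Gaussian noise (sd 0.02, the order of
wire-vs-model agreement spreads), clipped to (0, 1].

Passing tests on this cohort therefore demonstrate *self-consistency of
the method chain* (generation, calibration, identification, measurement,
evaluation), not clinical accuracy: the generator does not reproduce real
anatomical statistics (LAD/LCX/RCA frequencies, eccentric or serial or
diffuse lesions), image segmentation error, 3D secondary-flow losses,
pulsatility, or pressure-wire artifacts. Healthy distal FFR in these trees
bottoms out near 0.72 purely from diffuse Poiseuille loss along long
distal paths — within the model's physics, at the low end of what is seen
clinically.

## Numerical notes and problem sizes

All internal computation is SI (m, Pa, m³/s); 1 mmHg = 133.322 Pa.
Structural tree defects are construction errors; value-level violations
are collected by `validate_tree()`. Degenerate inputs fail loudly: closed
lumens and exhausted calibration pressure raise errors naming the segment
or outlet; non-convergence is reported in the `convergence_report`, never
silently discarded.

The test suite exercises: 100 randomized stenosed trees (depth ≤ 5,
≤ 16 outlets) for solver–oracle equivalence at solver tolerance 1e-10
(worst relative flow error ~1e-9) and for the 1e-4 fixed-point certificate
at default settings; calibration round trips at 1e-10; and two 86-vessel
cohorts (noise 0 and 0.02) for end-to-end evaluation — the zero-noise
cohort must produce a perfect confusion matrix, and the AUC must equal the
exhaustive pairwise concordance. The full suite runs in well under a
minute on one core.

## Known limitations

* Steady, rigid-wall, Newtonian flow; no pulsatility or compliance.
* The linear lesion model underestimates losses of irregular, eccentric
  lesions (the optional expansion term is a first correction, not a
  replacement for 3D simulation).
* Microcirculation drains to zero venous pressure; no back-pressure or
  autoregulation model.
* The FFR_D comparator's total-flow constant is a documented stand-in and
  its absolute values should not be read as a validated clinical method.
* Cohort-level diagnostic numbers from the synthetic generator
  characterize the pipeline, not patients.
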