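---
title: "Simulated ischemic pseudo-ECGs: models, populations and classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated ischemic pseudo-ECGs: models, populations and classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pecgsim` builds, end to end, an in-silico test bed for the early detection
of acute myocardial ischemia from the electrocardiogram: calibrated
populations of human ventricular myocyte models, ischemia-modified single
cells and 1D fibers, pseudo-ECG synthesis, automatic biomarker delineation,
and neural-network classifiers that detect and grade ischemic severity from
the pseudo-ECG features. This vignette documents the science and the design
decisions; the README shows the worked example.

## The cellular model and its ischemia overlay

The cellular substrate is the ten Tusscher–Panfilov 2006 (TP06) human
ventricular myocyte model in its epicardial parameterisation: 19 state
variables (membrane potential, Hodgkin–Huxley gates, intracellular Na⁺, K⁺
and a three-compartment Ca²⁺ subsystem with ryanodine-receptor release).
The epicardial variant is the conventional choice for pseudo-ECG work on
homogeneous fibers; the cell type enters only through a handful of
parameters, and the right-hand side is written so that other
parameterisations can be added.

Acute ischemia is represented by its three textbook cellular components,
each graded by a severity preset:

* **hypoxia** — an ATP-sensitive potassium current
  \(I_{K(ATP)} = f_{K(ATP)}\, G_{K(ATP)}\, ([K^+]_o/5.4)^{0.24} (V-E_K)\)
  with \(G_{K(ATP)} = 0.064\) mS/µF;
* **acidosis** — a constant multiplier \(f_{inhib}\) on \(I_{Na}\) and
  \(I_{CaL}\);
* **hyperkalemia** — elevated extracellular potassium \([K^+]_o\), entering
  every potassium-dependent reversal potential and current (including the
  \(\sqrt{[K^+]_o/5.4}\) factors of \(I_{K1}\) and \(I_{Kr}\) and the
  Na⁺/K⁺-pump saturation), so the resting membrane depolarises as
  \([K^+]_o\) rises.

The presets are control \((0,\,1,\,5.4\ \mathrm{mM})\), mild
\((0.1,\,0.875,\,6.25\ \mathrm{mM})\) and severe \((0.2,\,0.75,\,9.0\
\mathrm{mM})\); mild is the mid-point between no ischemia and the severe
stage. Only these presets are treated as normative; intermediate severities
can be expressed through `ischemia_spec()` but are not interpolated
automatically. \(I_{K(ATP)}\) carries potassium, so it is included in the
intracellular K⁺ balance alongside the stimulus charge, keeping the model's
charge bookkeeping consistent.

## Numerics

The production integrator is a dual-step operator-splitting scheme written
in C++: Rush–Larsen exponential updates for the eleven voltage-dependent
gates (plus the Ca²⁺-dependent `fCass` gate) and forward Euler for the
membrane potential, concentrations and release machinery. Two integer-
aligned step sizes are used — 0.02 ms whenever |dV/dt| exceeds 1 mV/ms (and
during the stimulus) and 0.1 ms elsewhere — so runs are bit-reproducible
and roughly five times cheaper than a uniform fine step. Voltage-dependent
coefficients are pre-tabulated on a 0.05 mV grid and linearly interpolated,
the standard trick of cardiac tissue simulators.

A stiff adaptive reference path (`pace_cell_reference()`,
`simulate_cable_reference()`; lsoda at relative tolerance \(10^{-3}\) and
absolute tolerance \(10^{-6}\), a banded Jacobian for the cable) integrates
the same right-hand side and serves as the validation oracle: on the
baseline model the refined-step splitting scheme agrees with it to within
2% on APD90, RMP and conduction velocity. The production 0.02 ms step
underestimates conduction velocity by ~4% and overshoots the upstroke peak
by ~5% relative to the converged values — a deliberate trade documented by
the validation tests; both biases are far inside the population spread of
those quantities and are identical across the conditions that the study
compares. The \(I_{CaL}\) Goldman–Hodgkin–Katz factor is evaluated through
its series limit near \(V = 15\) mV to avoid the removable singularity.

The cable is the method of lines on a homogeneous fiber of length 2 cm with
0.02 cm node spacing (101 nodes), second-order central differences and
no-flux ends, stimulated at the first three nodes. The printed diffusivity
source gives \(1.171\times 10^{-3}\) in cm²/s; taken literally this
produces conduction some thirty times slower than the conduction
velocities reported alongside it, so the package interprets the value as
cm²/ms, which reproduces the ~60 cm/s control scale. The explicit
diffusion step obeys \(D\,\Delta t/\Delta l^2 \le 1/2\) and the solver
refuses configurations that violate it.

## Populations of models

Inter-subject variability is modelled by scaling the twelve TP06 maximal
conductances and peak currents with multipliers drawn in \([0,2]\) by Latin
hypercube sampling (`lhs::randomLHS`, seeded). Each candidate is paced for
200 beats at 430 ms and 600 ms cycle length; a candidate is excluded when
its action potential amplitude is below 0 mV, its resting potential above
−64 mV or its upstroke longer than 10 ms (criteria applied in that order,
first failure recorded), and calibrated by requiring APD90 inside the
closed experimental monophasic ranges [170, 240] ms at CL 430 and
[195, 290] ms at CL 600 at *both* rates. A candidate rejected at the first
rate is not paced at the second; acceptance is nevertheless a pure function
of the per-rate biomarkers, which the audit trail stores.

**APD90 convention.** The source formulation measures amplitude with
respect to zero and takes APD90 as the time at which the potential falls to
10% of that amplitude (a level of a few mV above zero). This differs from
the textbook 90%-repolarisation-toward-RMP convention, and the difference
matters: under the literal convention the baseline model yields APD90 of
about 213 ms (CL 600) and 186 ms (CL 430) and passes calibration, and
accepted-population means land on the reported ~233 ms scale; under the
textbook convention the baseline gives 292/267 ms and would be rejected by
its own calibration range. The literal convention is therefore the default
(`apd_method = "apa10"`), with `"repol90"` available for sensitivity
analysis. Upstroke time is stimulus onset to peak (a 10–90% rise-time
variant is available).

At the published scale (10 000 samples) the acceptance rate is ~20%; the
package reproduces 18–24% at reduced scale (the acceptance suite uses 1400
samples, its own choice of problem size, yielding >250 accepted models).

## Pseudo-ECG and delineation

The extracellular potential at a virtual unipolar probe on the fiber axis,
2 cm beyond the cable end, is
\(\Phi_e(l') = A\int (-\partial V/\partial l)\,
\partial_l\big(1/|l-l'|\big)\,dl\)
over cells 15–85 (0-based from the stimulated end), with central-difference
gradients and trapezoidal quadrature; \(A = 1\) since the scale cancels in
ratio features. The sign convention makes a depolarisation wave travelling
toward the probe produce a positive deflection, so the QRS complex is
upright. On a *homogeneous* fiber repolarisation travels in the same
direction as activation (measured repolarisation times increase
monotonically along the cable), so the T wave is discordant — opposite in
sign to the QRS. Upright T waves require repolarisation-sequence reversal,
i.e. intrinsic APD heterogeneity, which these fibers deliberately do not
have. All delineation logic is therefore polarity-agnostic: waves are
located on |Φe| and amplitudes are reported with their sign.

Six biomarkers are measured per beat: QRS duration, QT interval, ST
deviation (the raw signal value midway between QRS end and T-wave onset; no
DC correction), T-wave duration, QRS amplitude and T-wave amplitude. Wave
onsets and ends are 10%-of-peak flank crossings, linearly interpolated, with
sub-threshold gaps shorter than 10 ms merged so notched and biphasic
complexes are treated as one wave. Two choices deserve comment:

* **T-wave threshold reference.** Homogeneous-fiber signals carry a shallow
  ramp between QRS and T (the slow plateau decline seen through the
  activation-time gradient). A threshold referenced to the T wave's own
  peak drags T onset into that ramp and produces control T durations of
  90–140 ms and QT ≈ 330 ms — irreconcilable with the reported population
  values (T duration 33.8 ± 12.2 ms, QT 264.3 ± 26.8 ms, i.e. QT minus
  T duration ≈ APD90, placing T onset at the first cells' APD90 instant).
  Referencing the T-wave flank threshold to 10% of the *QRS* peak
  magnitude separates the T deflection proper from the ramp and reproduces
  the reported scales; it is the default (`t_reference = "qrs"`), with the
  per-wave variant behind `t_reference = "wave"`. The choice was made on
  agreement with the reported population statistics.
* **Degenerate ratios.** The ratio of change \(b' = b_I/b_C\) is undefined
  when the control value is essentially zero (ST deviation of a healthy
  fiber). Below a floor of \(10^{-6}\) of the control QRS amplitude the
  ratio is replaced by the signed difference and the substitution recorded
  per model.

Conduction velocity uses activation times (first crossing of 0 mV) at 0.4
and 1.6 cm.

## Feature tables and cable protocol

For each accepted model the pipeline simulates a control cable and one
fully ischemic (2 cm zone) cable per severity, each paced at CL 600 ms, and
emits one labelled example per (model, severity): six magnitudes and six
ratios of change against the model's own control cable (control rows carry
ratios of exactly 1, the in-deployment meaning of "no change from
baseline"). Regional ischemia uses a central zone flanked by 0.1 cm linear
transitions, truncated at the fiber ends so the 2 cm zone is fully
ischemic; zone sizes 0.5–2 cm reproduce the depolarisation/repolarisation
dichotomy (QRS-linked biomarkers monotone in zone size, T-linked biomarkers
with an interior extremum).

The reference protocol paces cables for 30 beats. The acceptance suite
uses 5-beat cables for its 150-model feature sweeps (its own reduced
problem size): on the baseline model every biomarker agrees with the
30-beat protocol to within a few percent, the residual drift is common to
the conditions being compared, and an odd beat count avoids saving a
dropped beat if severe ischemia produces 2:1 capture. Models whose severe
cable blocks (elevated resting potential plus a weak sodium current —
roughly one accepted model in ten) are skipped and recorded; warm-starting
cables from single-cell steady states was evaluated and rejected, because
the sodium-loaded control steady state *promotes* block in severe fibers
that conduct from the published resting state.

## Classifiers

Three fully connected perceptrons with rectified-linear hidden units and
sigmoid outputs are trained by full-batch gradient descent on a
weight-decay-regularised binary cross-entropy (summed over output units):
a multi-class network (`ann1`, six magnitudes → one-hot control/mild/severe,
arg-max decision), and a cascade of a detection network (`ann21`,
magnitudes → control vs ischemic) and a grading network (`ann22`, ratios →
mild vs severe), thresholded at 0.5. Examples are split 75/25 into training
and evaluation sets (stratified by class; one split shared by all
networks), with 10-fold cross-validation on the training split. The
selection criterion is mean validation F1 across folds, ties toward fewer
parameters; by default the best fold's weights are carried to evaluation
(the literal reading of selecting "the weights that performed best"), with
refitting on the full training split behind `refit = TRUE`.

Defaults: learning rates 0.1 (`ann22`), 0.01 (`ann21`) and 0.005 (`ann1`),
preserving the reported ratios (the multi-class network trains 20× slower
than the grading network and half as fast as the detection network); weight
decay \(10^{-4}\); z-score feature normalisation fitted on training data
only; up to 20 000 epochs with early stopping when the relative cost
improvement over 500 epochs falls below \(10^{-8}\); macro-averaged Se/PPV
for the multi-class task. Weight initialisation is seeded He-scaled
uniform (\(\pm\sqrt{6/\mathrm{fan_in}}\), zero biases): with a fixed small
window such as ±0.1 the forward signal vanishes through 4–5 ReLU layers and
full-batch descent stalls permanently on a constant-output plateau at the
class-prior entropy, so "random small values" is read in the He sense that
rectified-linear practice requires. The default architecture grid crosses
4–5 hidden layers with 4, 7 or 8 units, covering the reported optima (5/7,
5/8, 4/4); `mlp_grid()` builds larger grids.

Feature attribution uses the Garson–Goh weight-magnitude scheme: absolute
weight matrices of all hidden layers are multiplied into one
input-to-last-hidden contribution matrix, each hidden pathway is normalised
by its inbound total, weighted by its absolute outbound weight, summed per
input and renormalised to 1; with one hidden layer this is Garson's
original tableau. A ridge logistic regression (`glmnet`) trained on the
same splits provides the baseline that the networks must beat on the hard
control-vs-mild contrast.

## What the synthetic data do and do not show

The generator reproduces the study conditions: conductance variability in
[0, 2], the three severity presets, homogeneous 1D fibers, a noise-free
far-field probe, and steady-state pacing at fixed rate. It does not emulate
transmural heterogeneity (hence the discordant T polarity), 3D anatomy and
torso effects, measurement noise, rate variability, or time-evolving
ischemia — so passing tests demonstrate internal consistency of the method
under the stated idealisations, not clinical performance. Classification
results at the reduced scale (150 models per class) are expected to sit
slightly below the values reachable with the full 2044-model population,
since the control/mild boundary sharpens with training data.

## Problem sizes used by the tests and the acceptance script

Chosen as the package's reduced-scale study: population of 1400 (tests) or
1000 (script) Latin hypercube samples, 200 pre-pacing beats per rate;
150–155 models per class with 5-beat cables for the classifier stage;
30-beat cables for the baseline severity battery and the 9-cable
zone-size sweep; architecture grid {4, 5} × {4, 8} at 5000 epochs for the
cascade. The full published scale (10 000 samples, 30-beat cables
throughout, the wide grid) is available through `study_config()` defaults.

## Known limitations

* The T wave of a homogeneous fiber is discordant; figures expecting
  clinical upright T waves will differ in sign (magnitude-based trends are
  unaffected).
* Models whose severe cable blocks are excluded from the classifier
  substrate, a survivorship filter the source material does not discuss.
* The production time step trades ~4% conduction-velocity bias for a ~5×
  speedup; use `solver_settings(dt_fast = 0.005, dt_slow = 0.02)` when
  absolute accuracy matters more than throughput.
* Single-fold weight carry-over after cross-validation is the literal
  reading of the selection rule; `refit = TRUE` usually performs slightly
  better.
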