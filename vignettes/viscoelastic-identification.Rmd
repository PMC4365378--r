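---
title: "Identifying viscoelastic models of collagen gels under compression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying viscoelastic models of collagen gels under compression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(viscofit)
```

## The problem

Collagen gels are the workhorse scaffold of vascular tissue engineering:
constructs matured in bioreactors are cyclically loaded, and anticipating
the stresses those strains generate requires a mechanical model of the
gel. Collagen gels are markedly viscoelastic — their load response depends
on strain rate and on the entire strain history — and nonlinear already at
the 15–25% compressions used in scaffold conditioning. This package
implements a system-identification treatment of that problem: viscoelastic
constitutive models are written as dynamic systems (input = programmed
strain or extension, output = measured load), their parameters are
estimated from sampled test records, and competing structures are compared
on independent validation records.

Because raw testing-machine records for such gels are rarely deposited,
the package also ships a synthetic-protocol module that generates the
standard test waveforms (constant-speed ramps, triangular strain cycling,
step relaxations) and simulates any of the model structures on them with
seeded measurement noise. All recovery claims made by the test suite and
the acceptance script are self-consistency claims on such synthetic
records; see "What the synthetic data does and does not show" below.

## Kinematics and conventions

For a sample of reference thickness $e_0$ (mm) compressed to extension
$e(t)$, the package uses the true strain $\varepsilon = (e - e_0)/e$, the
engineering strain $\varepsilon_{eng} = (e - e_0)/e_0$ and the stretch
$\lambda = e/e_0 = (1 - \varepsilon)^{-1}$. Compression means $e < e_0$,
so all strains are negative and $\lambda < 1$; protocol descriptors
(`protocol_spec`) instead take positive compression magnitudes in
engineering strain, which is what a testing-machine operator programs. The
conversion happens once, when the protocol waveform is built.

Units are seconds, millimetres and newtons throughout; the cross-section
$A_0$ (default 700 mm²) enters only when loads are converted to stresses
for the Mooney–Rivlin diagnostic. The sample thickness is not a quantity
the identification is sensitive to — all estimators work on strain — so
the configurable default $e_0 = 5$ mm only rescales extension inputs.

## The model family

All four structures are two Maxwell bodies (spring $g_i$ in series with a
dashpot, relaxation time $\tau_i = \eta_i / g_i$) in parallel, driven
through different springs:

* **Linear**: the classical two-Maxwell model in strain,
  $$\ddot y + a_1 \dot y + a_2 y = b_0 \ddot u + b_1 \dot u, \qquad
    u = \varepsilon,$$
  with $a_1 = (\tau_1+\tau_2)/\tau_1\tau_2$, $a_2 = 1/\tau_1\tau_2$,
  $b_0 = g_1 + g_2$, $b_1 = g_1/\tau_2 + g_2/\tau_1$
  (`maxwell_to_tf`). Its poles are $-1/\tau_i$, which is how relaxation
  time constants are read off an identified transfer function
  (`poles_to_time_constants`).

* **Model 1 (Mooney–Rivlin-inspired)**: the Maxwell pair is driven by the
  memoryless nonlinear spring extension
  $$e' = \left(C_1 + C_2 \frac1\lambda\right)\left(\lambda^2 -
  \frac1\lambda\right),$$
  the uniaxial Mooney–Rivlin stress–stretch form, with states
  $\dot x_i = (e' - x_i)/\tau_i$ and load
  $y = [g_1(e' - x_1) + g_2(e' - x_2)]\,(e_0/e)$. With $C_2 = 0$ this is
  the **Neo-Hookean** variant.

* **Hammerstein (model 2)**: a memoryless cubic
  $f(\varepsilon) = p_0\varepsilon^3 + p_1\varepsilon^2 + p_2\varepsilon$
  feeding the linear two-Maxwell block — the classic block-oriented
  Hammerstein structure. With $p = (0, 0, 1)$ it reduces exactly to the
  linear model, which is the nesting the model-selection tests exploit.

```{r}
p <- gel_reference_params("model1")
p
```

The `gel_reference_params` sets are representative fitted constants for
collagen gels (cyclic model-1 and Hammerstein sets, the Neo-Hookean
variant, linear cyclic time constants, and 25%/50% relaxation time
constants); they are the default generating truths of the synthetic
studies.

## Forward simulation: exact first-order-hold integration

Both nonlinear structures are linear in their internal states once the
memoryless input block has been applied. The package therefore never uses
a variable-step ODE solver in the loop: the input is read as piecewise
linear between samples (first-order hold — exactly what a constant-speed
crosshead produces), and each integration step has a closed form. Real
distinct poles are simulated by two exact scalar recursions (evaluated by
`stats::filter` at C speed); complex or repeated poles fall back to a
matrix-exponential stepping. This makes every simulation deterministic to
machine precision and roughly two orders of magnitude faster than `lsoda`
inside a Levenberg–Marquardt loop, which is what makes the Monte-Carlo
acceptance runs cheap. The test suite cross-checks the simulator against
`deSolve::lsoda` on the nonlinear model and against the closed-form
two-exponential relaxation on the linear one.

One numerical subtlety: in model 1 the nonlinearity $e'(\lambda)$ is
curved between samples even though $e(t)$ is piecewise linear.
`simulate_model1` therefore refines the extension grid by a factor of 4
(argument `refine`) before applying the nonlinearity, which is what makes
halving the sampling step change the output by less than $10^{-6}$ in
relative sup-norm at the protocol sampling rates.

Degenerate inputs are rejected where the model demands it: extensions must
stay strictly positive (the model-1 output has $e$ in a denominator),
$\tau_1 = \tau_2$ is refused rather than handled by the confluent
$t e^{-t/\tau}$ form (two distinct bodies are assumed), and initial states
default to zero — an unloaded sample at $t = 0$.

## Identification

### Linear: continuous-time instrumental variables

`srivc(dataset)` estimates $(a_1, a_2, b_0, b_1)$ directly in continuous
time, in the simplified refined IV style: signals are passed through a
state-variable filter so that filtered derivatives are obtained without
differencing noise; an initial least-squares estimate seeds an iteration
in which both the prefilter and the instruments — the noise-free simulated
output of the current model — are rebuilt from the current denominator
estimate, until the parameters move by less than `tol` (default $10^{-6}$
relative, cap 50 iterations). Instead of guessing a single filter cutoff,
a small log-spaced grid of cutoffs (default 6, spanning record length to a
tenth of the sampling rate) is tried for the initial step and the
candidate whose stabilized model best reproduces the measured output wins;
this removes the one genuinely arbitrary tuning knob of the scheme.
Unstable iterates are reflected into the stable region (with a warning if
the final estimate needed it), and an input that does not excite the
system — a constant, for instance — is a rank-deficiency error, not a
silent garbage estimate.

### Nonlinear: grey-box prediction-error minimisation

`fit_greybox(dataset, structure, init, fixed)` minimises
$\sum_k (y_{meas}(t_k) - y_{model}(t_k))^2$ by Levenberg–Marquardt
(`minpack.lm::nls.lm`, numeric Jacobians), with a full forward simulation
per residual evaluation. Positive parameters ($g_i$, $\tau_i$) are
optimised on the log scale. If a trial step produces an unsimulable
parameter set, the residual callback returns a large finite penalty, so
the step is rejected and the damping increases — the optimizer backs off
rather than crashing.

Two exact identifiability ridges make normalization mandatory, and the
package treats them as first-class facts rather than nuisances:

* model 1: $(C_1, C_2, g_1, g_2) \to (kC_1, kC_2, g_1/k, g_2/k)$ leaves
  the output invariant for any $k > 0$;
* Hammerstein: the analogous $(p, g) \to (kp, g/k)$ ridge.

The test suite demonstrates both numerically (two unnormalized fits
started on the same ridge reach indistinguishable loss with very different
parameters). Consequently a grey-box fit should fix one scale parameter
(`fixed = "C2"` for model 1, `"C1"` for the Neo-Hookean variant,
`"g1"` for Hammerstein), and — following the identification procedure used
for these gels — the time constants of a model-1 fit are usually fixed at
the values of a prior linear fit, with the option to release them.

When no initial values are supplied, a seed-controlled random
initialisation is drawn log-uniformly (positive parameters) and uniformly
(sign-free constants) within broad physical bounds; the self-consistency
experiments instead initialise at twice the generating values, which is a
deliberately hostile-but-reproducible starting point.

### Validation and model comparison

`validate(fit, newdata)` applies the measured input of an *independent*
record to the identified model and scores the simulated output with
$$\mathrm{FIT} = 100\left(1 - \frac{\lVert y_{model} - y_{meas}\rVert}
{\lVert y_{meas} - \bar y_{meas}\rVert}\right),$$
Euclidean norm over the whole record (the norm is a choice; the package
documents and uses the Euclidean one). Records sharing the identification
label are refused — validation is never a re-fit. Model structures are
ranked on identification data by the Akaike final prediction error
$\mathrm{FPE} = (V/N)(1 + d/N)/(1 - d/N)$ with $d$ free parameters, the
standard definition used by the classical identification toolboxes,
computed on the cycling part of the record only (the first compression and
the cycling are analysed separately; `split_first_compression` cuts the
record at the first touch of the lower cycle bound).

The Mooney–Rivlin linearization diagnostic (`mr_linearize`) plots
$1/\lambda$ against $\sigma/(\lambda^2 - 1/\lambda)$: data obeying the
Mooney–Rivlin law fall on a line with intercept $C_1$ and slope $C_2$, a
flat line is the Neo-Hookean signature, and the transform is singular at
$\lambda = 1$, so a guard band $|\lambda - 1| < 0.01$ (configurable) is
excluded. In the cyclic workflow this diagnostic doubles as the source of
the fixed scale constants, which keeps the normalization data-driven.

## The synthetic protocols

`protocol_spec` + `make_ramp` / `make_cycles` / `make_step_relaxation`
generate the three standard waveforms as piecewise-linear extension
profiles with breakpoints exactly at phase boundaries:

* ramps at 0.1–1.0 mm/min to 20% engineering strain;
* an approach ramp to the 20% cycle mean followed by eight triangular
  cycles between 15% and 25% (each cycle mean → high → low → mean, so the
  cycling phase lasts exactly $n \cdot 2\Delta e / v$);
* step relaxations at 10 mm/min to 25% or 50% strain, held 1800 s.

Default sampling rates are 10 Hz for ramps/cycling and 1 Hz for the long
relaxations — rates that keep a record at desk scale (5 401 and 1 816
samples respectively) while still resolving the fastest reference time
constant ($\tau_1 \approx 1$ s) marginally. `generate_dataset` simulates a
chosen truth on the waveform and adds i.i.d. Gaussian noise to the load
only (strain is machine-commanded), defaulting to 1% of the peak absolute
load; the seed and full provenance are stored in the record's metadata, so
a dataset is bit-reproducible from its metadata.

### What the synthetic data does and does not show

The generator reproduces the *protocols* and a plausible sensor-noise
floor, and the default truths are the reference parameter sets — so
passing recovery tests shows that the estimators invert the package's own
forward models reliably under realistic excitation, record lengths and
noise. It does not emulate machine compliance, slippage, temperature
effects, sample-to-sample biological variability, or any mismatch between
the model family and a real gel; agreement on synthetic records therefore
bounds estimator quality, not model adequacy for a particular material.

## The end-to-end workflows

`run_relaxation_study()` generates the 25% and 50% step-relaxation
records, identifies the linear transfer function on each with `srivc`, and
reports recovered time constants next to the generating ones together with
the maximum absolute model-vs-data error.

`run_cyclic_study()` mirrors the full campaign: four eight-cycle records
at 1.0 / 0.5 / 0.5 / 0.1 mm/min, identification on the fastest record
(sample 1 — the fastest excitation is the one that excites all dynamic
modes), validation by FIT on samples 2–4, FPE ranking on the cycling part
of sample 1:

```{r, eval = FALSE}
study <- run_cyclic_study(truth = "hammerstein", seed = 10)
print(study)
```

With a Hammerstein truth the Hammerstein structure wins both by validation
FIT and by FPE; with a linear truth every structure sits near the noise
ceiling and the Hammerstein fit coincides with the linear one (the nesting
property). These are the qualitative model-selection behaviours the
acceptance suite asserts.

## Problem sizes and reproducibility

The simulation studies in the tests and the acceptance script use the
protocol defaults above: eight-cycle records of 5 401 samples (540 s at
10 Hz), relaxation records of 1 816 samples (15 s ramp + 1 800 s hold at
1 Hz), 1% load noise and 10 noise seeds per recovery experiment, medians
reported. A single grey-box fit on a cyclic record takes well under a
second, so the complete acceptance run is a matter of seconds. Every
random draw is seed-controlled; `scripts/acceptance.R --seed N` shifts all
seeds reproducibly.

## Known limitations

* Two Maxwell bodies only; no parallel equilibrium spring, so every
  structure relaxes to zero load under a held strain. Materials with a
  nonzero equilibrium modulus need an extended structure.
* $\tau_1 = \tau_2$ is rejected rather than handled confluently.
* The SRIVC implementation is fixed at the second-order, $(b_0, b_1)$
  numerator structure of the two-Maxwell family rather than general
  orders.
* The grey-box estimator is local: pathological initialisations can reach
  local minima, which is why the normalization conventions and the
  linear-fit-seeded initialisation are the documented default procedure.
* FIT is computed over whichever record is passed; whether the first
  compression should be excluded from validation is a modelling choice —
  `split_first_compression` makes either convention one line of code, and
  the full record is the default.
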