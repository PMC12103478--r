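---
title: "Lower-limit closed-loop vasopressor delivery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lower-limit closed-loop vasopressor delivery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pressorloop)
```

## The control problem

Intraoperative hypotension is conventionally defined on the mean blood
pressure: MBP below 65 mmHg. Under routine anesthesia blood pressure is
observed intermittently — an oscillometric cuff reading every 2.5 min — so
a dosing controller gets one decision point per epoch, with measurement
noise and occasional cuff failures. The objective is *lower-limit control*:
keep MBP above the threshold, not near a target. This distinction matters
both for the control law (no proportional tracking; act only on threshold
crossings) and for evaluation (Varvel's set-point indices can rank a
trajectory hugging the limit as "worse" than one riding far above it, even
when both satisfy the limit 100% of the time; `lower_limit_compliance()`
exists for exactly this reason).

## The controller state machine

`step_controller()` is a pure function of `(state, reading, weight,
config)`. The state is the machine's entire memory: mode (NORMAL or
VASOPRESSOR), boluses given this episode (0–2), current infusion rate, the
rate remembered across a suspension, and the suspension clock. The rules:

1. An invalid reading changes nothing (`frozen`). A spuriously low or high
   *valid* reading is not rejected: every reading recomputes the rate, so a
   one-off artifact self-corrects at the next epoch.
2. NORMAL, MBP < 65: enter vasopressor mode, bolus `min(0.002 mg/kg × weight,
   0.1 mg)`.
3. Vasopressor mode, one bolus given, MBP < 65 again: half the entry bolus,
   infusion starts.
4. With the infusion running, the rate is adjusted once per reading (below).
   MBP > 85 suspends the infusion (rate 0, rate remembered, clock started);
   MBP back at or below 85 resumes from the remembered rate.
5. A suspension lasting more than 15 min exits vasopressor mode and resets
   every counter.

All comparisons are strict, mirroring the clinical definitions: MBP equal
to 65 is adequate, MBP equal to 85 maintains the infusion, SBP above 140 is
hypertensive, and the exit comparison is `duration > 15 min` measured from
the reading that caused the suspension.

### The infusion-rate policy

The in-device rate formula of the clinical system is unpublished ("a rate
determined by the protocol"); the policy here is this package's own stated
stand-in, chosen for plausibility and fully configurable via
`controller_config(rate_policy = ...)`:

| parameter | default | meaning |
|---|---|---|
| `r0_per_kg` | 0.01 mg/kg/h | initial rate at infusion start (0.7 mg/h at 70 kg, the order of magnitude of reported mean automated-arm dosing) |
| `step_up` | ×1.25 | applied while MBP < 65 |
| `step_down` | ×0.8 | applied in the 75–85 mmHg band |
| `band_low` | 75 mmHg | start of the step-down band; 65–75 holds |
| `floor_frac` | 0.2 | rate never steps below `0.2 × r0` while running |

Rates are quantized to the syringe-pump resolution of 0.1 mL/h — 0.005 mg/h
at the default 0.05 mg/mL concentration — and capped at 2 mg/h.

### Decisions where the rules were genuinely open

* **Exit and re-entry on the same reading.** When the reading that exceeds
  the 15-min suspension timeout is itself hypotensive, the implementation
  exits first and immediately re-enters with a *full* entry bolus. The
  alternative (exit only; wait one epoch) delays treatment by 2.5 min for
  no clinical benefit.
* **Re-bolusing across episodes.** Whether the clinical device repeats the
  entry bolus on a later episode within the same case is unstated; this
  implementation does, because mode exit resets all counters.
* **Suspension clock with no infusion running.** After a single bolus and
  recovery above 85 mmHg, the clock runs with a remembered rate of zero, so
  a quiet episode still terminates after 15 min. Between 65 and 85 mmHg
  with only one bolus given, nothing is infusing and nothing is titrated.
* **The upper safety limit** that deactivates dosing is identified with the
  85 mmHg suspension threshold — the only printed upper limit that governs
  the device. Hypertension (SBP > 140) is classified by the metrics but
  never treated; that is out of the controller's mandate.

## The virtual patient

No patient model accompanies the clinical system (its control law is
deliberately model-free), so the simulator is a test harness with no claim
to physiological fidelity. Simulated MBP is additive:

$$\mathrm{MBP}(t) = B - D\,(1 - e^{-t/\tau}) - \sum_j d_j\,\mathbf{1}[t \in
\text{dist}_j] + E_{\max}\frac{C(t)}{C_{50} + C(t)}$$

with awake baseline $B$ (default 95 mmHg), anesthetic depression $D$
(18 mmHg, onset time constant $\tau = 5$ min), rectangular disturbances,
and a saturating pressor effect driven by the one-compartment effect-site
amount $C(t)$: a bolus contributes $\text{dose}\cdot e^{-k_e(t-t_b)}$, an
infusion segment at $r$ mg/h contributes $\frac{r/60}{k_e}(1 -
e^{-k_e\,\Delta t})$ carried forward with decay. Because the PK is linear,
$C(t)$ is evaluated analytically at the measurement instants — no ODE
stepping, no discretization error; the test suite cross-checks the closed
forms against `deSolve::lsoda` integration.

Defaults $k_e = 0.2/\text{min}$, $E_{\max} = 25$ mmHg, $C_{50} = 0.05$ mg
give a 0.1 mg bolus a ~17 mmHg peak effect with a ~3.5 min effect
half-life, and a 0.7 mg/h infusion a ~13 mmHg steady-state effect —
plausible magnitudes for epoch-scale dynamics, but placeholders, not
clinically validated parameters, and they must not be read as such.

Measurements add Gaussian noise (SD 3 mmHg) to the true MBP, derive SBP
through a pulse-pressure model `sbp = mbp + 25 + 0.25·mbp` (so the SBP > 140
classification is exercisable) and close `mbp = dbp + (sbp − dbp)/3` for
DBP. Cuff failures are i.i.d. Bernoulli per epoch (2%); real artifact
bursts are correlated, which this deliberately does not model.

`sample_cohort()` draws weight ~ Normal(65, 12) truncated above 40 kg,
baseline ~ Normal(95, 10), anesthetic drop ~ Normal(18, 4) truncated above
5, one to five disturbances per case (depth 5–25 mmHg, duration 5–40 min)
and case length Uniform(90, 360) min, spanning reported intraoperative
duration ranges. The `manual-like` arm caricatures delayed human response:
the entry bolus arrives one epoch late with probability 0.5 and no infusion
is titrated. It is a comparison device for simulation experiments only, not
a model of anesthesiologist behavior.

**What passing simulations do and do not show.** They demonstrate that the
state machine implements its rules, that the loop closes (dosing raises
simulated pressure, which changes subsequent dosing) and that under these
synthetic conditions automation reduces hypotension time versus no or
delayed treatment. They say nothing about effect sizes in real patients:
the simulator has no baroreflex, no cardiac output, no drug interactions,
and rectangular disturbances.

## Endpoint metrics

"Percentage of time" is operationalized as the percentage of *valid*
2.5-min epochs — each reading represents its epoch, missing readings are
excluded from numerator and denominator alike, and no interpolation is
attempted (none would be defensible for intermittent cuff data). The
adequate percentage is computed by subtracting the percentage of the
*union* of hypotensive and hypertensive epochs, so an epoch that is both
counts once there while counting toward both individual percentages.

Consecutive-hypotension runs are maximal runs of the hypotensive indicator;
a missing epoch breaks a run, because consecutiveness must be observed.
Run shares are reported both exactly and rounded half-up to integers, the
form in which such tabulations are usually quoted (29 of 53 runs → 54.7% →
55%).

Varvel indices use performance error $PE_i = 100\,(m_i - T)/T$ against a
reference $T$: MDPE = median, MDAPE = median absolute, wobble =
median$|PE_i - \mathrm{MDPE}|$, divergence = least-squares slope of
$|PE_i|$ on time (%/min).

## Inferential statistics

All inference runs on `(n, mean, SD)` summaries with the pooled-variance
Student t (df $= n_1+n_2-2$): this choice, rather than Welch, is the one
that algebraically matches published results computed from these summaries,
and `pooled_t_ci()` is by construction identical to
`t.test(var.equal = TRUE)` on any raw sample with the same moments (a
tested identity). Non-inferiority shifts the null by the margin in the
unfavorable direction — for a higher-is-better endpoint,
$t = (\hat\Delta + m)/se$ tested one-sided at $\alpha = 0.025$,
equivalently the one-sided 97.5% lower confidence limit of $\hat\Delta$
exceeding $-m$. The conclusion flag and the CI criterion are dual and
tested to agree on random inputs. Directions: adequate-time endpoints are
higher-is-better; hypotension- and hypertension-time endpoints are
lower-is-better.

`sample_size_note()` is a labeled planning aid (normal approximation,
dropout inflation by $1/(1-d)$); it does not reconstruct any particular
trial's enrolment because the planners' assumed SD is generally unprinted.

## Numerical and reproducibility choices

* Rate quantization rounds to the nearest pump step before capping;
  equality comparisons in tests allow for this quantum.
* `sample_cohort()` seeds a private RNG stream and restores the caller's
  seed; the file pipeline (`cmd_simulate()`) seeds one stream per
  (patient, arm) so that arm subsets and reruns are byte-identical, which
  the manifest records via MD5 checksums.
* Degenerate inputs fail loudly: zero valid epochs is an explicit
  undefined-endpoint error, not an NaN; unordered reading times, malformed
  CSV schemas and inconsistent states are rejected with messages naming
  the offense.
* Problem sizes in the test suite — 1,000 random trajectories for the
  controller properties, 1,000 label sequences for the metric oracles,
  10,000 simulated trials for type-I calibration, 200 virtual patients ×
  3 arms for the closed-loop comparison — were chosen to make Monte-Carlo
  error small relative to the effects being checked while keeping a full
  run in the order of a minute.

## Known limitations

* The infusion-rate policy is a stand-in; conclusions that depend on its
  exact shape (e.g. total dose delivered) are properties of this package,
  not of the clinical device.
* The virtual patient is deliberately minimal; see above for what it does
  not model.
* Epoch weighting is uniform; if a case mixes measurement intervals (e.g.
  manual re-measurements between cycles), all epochs still count equally.
* The metrics treat the supplied trajectory as the evaluation window;
  anchoring the window to anesthetic start/stop times is the caller's
  responsibility (`endpoint_percentages(window = ...)`).
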