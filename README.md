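# pressorloop

Intraoperative hypotension — mean blood pressure (MBP) below 65 mmHg during
surgery — is associated with postoperative organ injury, and treating it
promptly with a vasopressor such as phenylephrine is routine anesthetic
practice. In ordinary cases blood pressure is only measured intermittently,
by an arm cuff every few minutes, so a practical automated system must make
one dosing decision per noninvasive blood-pressure (NIBP) reading rather
than titrating continuously against a set-point.

`pressorloop` implements such a system as testable software, for
anesthesia-informatics researchers and control-engineering students:

* **Controller** — a deterministic *lower-limit* control state machine.
  It holds MBP *above* a threshold instead of tracking a target. On the
  first reading with MBP < 65 mmHg it enters vasopressor mode and commands
  a bolus of 0.002 mg/kg (capped at 0.1 mg); if hypotension persists at the
  next 2.5-min reading it gives half that bolus and starts a continuous
  infusion (maximum 2 mg/h of 0.05 mg/mL solution), which is then stepped
  up, held, or stepped down once per reading. Above 85 mmHg the infusion is
  suspended; a suspension longer than 15 min ends the episode. Failed cuff
  measurements freeze the control state.
* **Virtual patients** — a seeded simulator (one-compartment drug amount
  with a saturating pressor effect, additive anesthetic depression and
  hypotensive disturbances, Gaussian cuff noise, Bernoulli cuff failures)
  so the closed loop can be exercised end-to-end without clinical data.
* **Metrics** — per-patient time-in-range percentages over valid 2.5-min
  epochs (adequate = MBP > 65 and SBP < 140), consecutive-hypotension run
  tabulations, Varvel performance-error indices (MDPE, MDAPE, wobble,
  divergence), and lower-limit compliance.
* **Statistics** — pooled-variance two-sample t machinery operating
  directly on `(n, mean, SD)` group summaries: confidence intervals and
  margin-shifted non-inferiority tests
  (`t = (diff + margin) / se`, one-sided, df = n₁ + n₂ − 2),
  plus a normal-approximation sample-size planner.

## Worked example

Reproducing a published two-arm comparison (automated vs manual dosing,
n = 11 vs 9) of the adequate blood-pressure time percentage from its group
summaries alone:

```r
library(pressorloop)
s <- example_trial_summaries()
noninferiority_test(s$adequate_bp$automated, s$adequate_bp$manual, margin = 10)
#> Non-inferiority t test (pooled variance, df = 18, higher-is-better)
#>   difference: 12.08%  (95% CI -0.12 to 24.28)
#>   margin: 10.0%  t = 3.802  one-sided p = 0.0006521
#>   conclusion: non-inferior
```

The 97.5% one-sided lower confidence limit of the difference is −0.12%;
because it stays above the −10% margin, the automated arm is non-inferior
(p < 0.001). Running one virtual patient through the closed loop:

```r
set.seed(42)
p <- patient_profile(disturbances = data.frame(onset = 20, depth = 22,
                                               duration = 35))
sim <- run_closed_loop(p, duration = 120, arm = "automated")
head(sim$actions[sim$actions$note != "none", ], 5)
#>    t_min bolus_mg rate_mg_h rate_ml_h        mode         note
#> 9   20.0     0.10      0.00       0.0 VASOPRESSOR  entry-bolus
#> 10  22.5     0.00      0.00       0.0 VASOPRESSOR         hold
#> 11  25.0     0.05      0.65      13.0 VASOPRESSOR second-bolus
#> 12  27.5     0.00      0.65      13.0 VASOPRESSOR         hold
#> 13  30.0     0.00      0.52      10.4 VASOPRESSOR    step-down

ep <- endpoint_percentages(classify_epochs(sim$trajectory))
#> adequate 85.7% | hypotensive 10.2% | hypertensive 4.1% (49 valid epochs)
```

The hypotensive disturbance starting at minute 20 triggers the entry bolus
(0.1 mg), the persistent low reading two epochs later triggers the half
bolus plus infusion start (0.65 mg/h = 13 mL/h of 0.05 mg/mL solution), and
the rate is then titrated per reading.

A command-line wrapper over the same functions lives at
`inst/cli/pressorloop.R` (subcommands `simulate`, `replay`, `evaluate`,
`trial`, `stats`).

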