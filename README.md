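# vibropalp

Objective metrics and simulation for **vibrotactile palpation skill
assessment**.

## The problem

Locating the point of maximum vibration over an arteriovenous fistula (AVF)
by touch is a core clinical skill for hemodialysis cannulation: a
well-functioning fistula produces a continuous "thrill", a failing one a
pulsatile sensation, and needles must be placed where the signal is felt.
Simulator studies of this skill record the index and middle fingertips with
a motion-capture sensor while a hidden motor renders controlled vibration
under varying haptic conditions — vibration **type** (pulse vs thrill),
**intensity** (strong vs weak) and artificial-skin **thickness**
(4 vs 6 mm) — at one of 8 possible target locations.

`vibropalp` is for researchers running or re-analyzing such studies. It
provides:

1. **Metrics** — five objective per-trial measures computed from the
   fingertip trajectory `(t, x, y, z)` and the known target `T = (T_x, T_y)`:
   - *accuracy* `a = min_f ||p_f(t_end) − T||` over fingers
     `f ∈ {index, middle}`, in the skin plane (mm), with bands
     accurate ≤ 10 mm < marginal ≤ 30 mm < error;
   - *duration* `t_end − t_0` (s);
   - *total path length* `TPL = Σ_i ||p_{i+1} − p_i||` in 3D (mm);
   - *ratio of correct movement*
     `RCM = 100 · #{i : V_p(i) > 0} / #movement frames`, where
     `V_p = v · (T − p)/||T − p||` is the velocity component toward the
     target and a movement frame has 3D speed ≥ 1 mm/s;
   - *error rate* — fraction of movement frames farther than 30 mm from
     the target.
2. **Models** — per metric, a participant-random-intercept linear mixed
   model `y_ij = μ_j + α₁ I_type + α₂ I_intensity + α₃ I_thickness + ε_ij`
   (REML, Wald 95% CIs), and for the binary within-30 mm outcome a
   logistic GLMM `logit π_ij = α_0j + α₁ I₁ + α₂ I₂ + α₃ I₃` fitted by
   adaptive Gauss–Hermite quadrature, with odds ratios `exp(α_k)`.
3. **Synthetic studies** — a seeded generator at two fidelities (direct
   metric draws from the generative models above, or kinematic fingertip
   trajectories run through the metrics engine), calibrated so that
   parameter-recovery simulations reproduce published effect sizes.

## Worked example

```r
library(vibropalp)

study <- simulate_study(12, seed = 1, fidelity = "metric")
analysis <- analyze_study(study$metric_table)
print(analysis)
```

```
<study_analysis> 384 trials, 12 participants
metric                       factor change     estimate  95% CI
accuracy (odds ratio)        pulse->thrill        1.391  (0.877, 2.208)
accuracy (odds ratio)        strong->weak         0.802  (0.506, 1.272)
accuracy (odds ratio)        4mm->6mm             0.610  (0.384, 0.969) *
duration_s (mean shift)      pulse->thrill       -5.674  (-7.249, -4.098) *
duration_s (mean shift)      strong->weak        10.027  (8.452, 11.602) *
duration_s (mean shift)      4mm->6mm             6.882  (5.307, 8.458) *
tpl_mm (mean shift)          pulse->thrill     -264.810  (-362.610, -167.010) *
tpl_mm (mean shift)          strong->weak       473.698  (375.898, 571.498) *
tpl_mm (mean shift)          4mm->6mm           526.170  (428.370, 623.970) *
rcm_pct (mean shift)         pulse->thrill       -0.189  (-0.730, 0.351)
rcm_pct (mean shift)         strong->weak        -0.861  (-1.402, -0.320) *
rcm_pct (mean shift)         4mm->6mm            -0.966  (-1.507, -0.426) *
error_rate (mean shift)      pulse->thrill       -0.000  (-0.024, 0.023)
error_rate (mean shift)      strong->weak        -0.001  (-0.025, 0.022)
error_rate (mean shift)      4mm->6mm            -0.005  (-0.029, 0.018)
```

Read each row as the estimated change in that metric when one haptic
factor moves off its referent level (pulse / strong / 4 mm), holding the
others fixed; `*` marks 95% CIs excluding 0 (excluding 1 for odds ratios).
In this simulated study, switching to a thrill stimulus shortens trials by
about 5.7 s and cuts about 265 mm of fingertip travel; a weak stimulus
slows participants down and degrades the share of movement directed at
the target (RCM), while the error rate responds to nothing — each
matching the directions encoded in the default generator.

One fitted odds ratio:

```r
fit <- fit_accuracy_glmm(study$metric_table)
odds_ratio(fit, "vibration_type")
#>  estimate    ci_low   ci_high
#> 1.3913458 0.8769247 2.2075362
```

The command-line pipeline wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "vibropalp.R", package = "vibropalp"))')
Rscript "$CLI" generate --participants 12 --seed 7 --fidelity trajectory --out bundle
Rscript "$CLI" metrics  --bundle bundle --out metrics.csv
Rscript "$CLI" analyze  --metrics metrics.csv --out results.json
Rscript "$CLI" recover  --replicates 100 --seed 1 --out recovery.json
```

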