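# neurostat

Autonomous DO-stat fed-batch fermentation control with neural baseline
recognition, in R.

## The problem

High-density *E. coli* cultivation feeds glucose by the **DO-stat**
strategy: when glucose is depleted the cells' oxygen uptake collapses and
dissolved oxygen (DO) spikes upward — the trigger to feed; as feeding
resumes, DO falls back — the trigger to stop. The natural way to express
these triggers is relative to the **DO baseline**, the level DO returns to
while substrate is present. But the baseline drifts continuously with
broth rheology, oxygen transfer and the culture's growing oxygen demand,
so fixed thresholds require a skilled operator to re-tune them throughout
the run.

`neurostat` replaces the operator. A multilayer perceptron (MLP)

```
DO window (60 min, 1/min)  →  1024 → 512 → 256 → 128 (ReLU)  →  baseline (%DO)
```

estimates the current baseline from the most recent hour of DO data. The
estimate stream is smoothed by a *causal* Savitzky–Golay filter
(trailing-window endpoint fit, order 2, window 15 min) into
`baseline_smooth`, and every control decision is taken relative to it:

* **Oxygen supply** (per minute): `baseline_smooth < baseline_lb` →
  agitation +20 rpm, airflow +0.05 L/min; `> baseline_ub` → one step down;
  clamped to [400, 800] rpm, [0.5, 1.5] L/min.
* **Glucose feeding** (per second): start a pulse at `v_glc` when
  `DO > baseline_smooth + threshold_increase`; stop when
  `DO < baseline_smooth + baseline_increase`; any pulse is force-stopped
  after 3 min (safety rule).
* **Nitrogen feeding**: latches on at the first glucose trigger
  (1.0 g/L/h, never stops).
* **Induction**: one-shot at `induction_time` — IPTG dose, temperature
  37 → 28 °C, and a stricter induction parameter set is loaded.

Because the baseline cannot be measured by any physical sensor, the MLP is
trained on a **synthetic corpus**: simulated DO traces with drifting /
ramping baselines, glucose-depletion spikes of varied height, width and
frequency, and sensor noise, each 60-minute window labeled with the
ground-truth baseline at its final minute. A minimal fed-batch plant
simulator (Monod growth, kLa-based oxygen transfer, lagged noisy sensor)
closes the loop for testing. The package also implements Taguchi range
analysis (level means `k`, ranges `R`) for the bundled L9(3^4)
induction-optimization experiment.

## Worked example

```r
library(neurostat)

## 1. Synthesize a labeled corpus and train the recognizer
ds <- generate_dataset(15000, do_gen_params(), seed = 42)
sp <- split_dataset(ds, ratio = 0.5, seed = 42)          # 7500 / 7500
model <- build_model(mlp_config(), seed = 42)
model <- train_baseline_model(model, sp$train,
                              training_config(seed = 42))
evaluate_model(model, sp$test)
#> <eval_metrics> n = 7500  R^2 = 0.9985  MSE = 0.9827 (%DO^2)

## 2. Run a fully autonomous 24-h fermentation in silico
run <- run_closed_loop(plant = plant_params(), model = model,
                       phase_params = phase_param_set(),
                       duration_h = 24, seed = 1)
run
#> <neurostat_run> 86400 recorded steps (24.0 h), 2492 logged events, seed 1
#>   final: biomass 22.28, glucose 0.007 g/L, volume 0.904 L
head(subset(run$events, event != "baseline_update"), 4)
#>     time_s          event detail
#> 336  23697     feed_start     21
#> 337  23697 nitrogen_start      1
#> 340  23761      feed_stop     64
#> 348  24202     feed_start     21

## 3. Range analysis of the bundled induction experiment
range_analysis(induction_l9())
#> <range_analysis>
#>   IT     R = 7.43e+07 | k[10] = 6.63e+08  k[15] = 5.89e+08  k[20] = 5.95e+08
#>   IA     R = 2.63e+07 | k[0.1] = 6.05e+08  k[0.3] = 6.11e+08  k[0.5] = 6.31e+08
#>   SSH    R = 1.44e+08 | k[15/10] = 5.53e+08  k[30/25] = 5.97e+08  k[50/45] = 6.97e+08
#>   ranking: SSH > IT > IA
#>   optimal: IT = 10, IA = 0.5, SSH = 50/45
```

The evaluation metrics read: on 7,500 held-out windows the recognizer
explains 99.85% of the baseline variance with a root-mean-square error of
about one percent DO. In the closed-loop run, the event log shows the
DO-stat engaging at 6.6 h: 555 short glucose pulses over the run (the
`detail` column of a stop event is the pulse duration in seconds, here
never above 72, far inside the 3-minute safety cutoff), the nitrogen
latch at the first trigger, and one induction event at 10 h with the
temperature shift to 28 °C. The range analysis ranks the feed start/stop
threshold (SSH) as the dominant induction-phase factor and picks
IT = 10 h, IA = 0.5 mmol/L, SSH = 50/45 as the optimal combination.

A command-line front end over the same functions is installed with the
package (`system.file("cli", "neurostat.R", package = "neurostat")`) with
subcommands `generate-data`, `train`, `evaluate`, `recognize`, `simulate`,
`plant-demo`, `analyze-doe`.

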