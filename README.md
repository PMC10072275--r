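# nmjCa

Quantitative analysis of compartment-specific Ca²⁺ imaging at the
*Drosophila* larval neuromuscular junction (NMJ).

Genetically encoded indicators report activity-evoked Ca²⁺ in different
presynaptic compartments — cytosolic GCaMP, ER-lumen sensors (which show
a fast release **dip** followed by slow uptake), and mitochondrial CEPIA
(fast uptake, partial decline, slow return) — plus postsynaptic
responses and spontaneous miniature events ("minis"). Comparing
wild-type and mutant terminals across stimulation frequencies requires a
reproducible trace-processing chain and a matched statistical scheme.
nmjCa packages that chain for anyone analysing widefield NMJ movies or
confocal marker images:

* **Preprocessing** — rolling-ball background subtraction (grayscale
  disc opening, radius 50 px), translation registration against the
  first frame, ROI mean-trace extraction, and the study's
  quality-control discard rules.
* **Trace analysis** — photobleach correction by a fitted power curve
  *PC(x) = a·xᵇ* (log–log OLS on pre-stimulation frames, then division
  of the whole time course), 5-frame rolling average, ΔF/F as
  corrected − 1, and evoked features: resting F, max F, ΔF, post-onset
  ΔF/F extrema, time to peak, 50%/100% recovery times.
* **Mini detection** — a robust-threshold event detector
  (3σ, MAD-based noise estimate) validated against simulated ground
  truth, with events/s frequency and maximum-amplitude readouts.
* **Static quantification** — Intermodes histogram thresholding, puncta
  vs NMJ-remainder partitioning, reference-channel ratiometry, and
  8-connectivity object sizes.
* **Statistics** — per-larva datapoints, Shapiro–Wilk-gated routing to
  Student's *t* / Mann–Whitney U or mixed-effects repeated-measures
  ANOVA (genotype × stimulation frequency, larva as random intercept),
  Tukey and Dunnett post-hoc tests, and the control-mean, batch, and
  timecourse (control range = 100) normalizations.
* **Synthetic data** — `simConfig()` / `simulateTrace()` /
  `simulateMovie()` / `simulateStaticPair()` / `simulateCohort()`
  generate recordings with full ground truth (kernel parameters, mini
  times, bleach coefficients, drift shifts), so every stage is testable
  without raw data.

## Worked example

Simulate a wild-type ER-lumen recording (10 frames/s, 5 s baseline,
2 s 40 Hz train, power-law bleaching, 2% noise) and run the full trace
pipeline:

```r
library(nmjCa)

cfg <- simConfig("er", seed = 42)
sim <- simulateTrace(cfg)
res <- analyzeTrace(sim$trace)
res$model
#> BleachModel: PC(x) = 1019.15 * x^-0.0568764  (fit frames 0..49, x = frame + 1)
res$features
#> EvokedFeatures:
#>  resting_F    max_F  delta_F   max_dff min_dff_post_stim time_to_peak_s
#>   815.8409 1077.688 261.8475 0.3292983       -0.06013312            8.2
#>  t50_recovery_s t100_recovery_s
#>            11.9              NA
```

The fitted curve recovers the simulated bleach (a = 1000, b = −0.05)
from 50 noisy baseline frames; `max_dff` ≈ 0.33 matches the simulated
uptake overshoot (true peak 0.3), `min_dff_post_stim` is the ER release
dip (−0.1 before the 5-frame smoothing attenuates it), time-to-peak is
measured from stimulation onset, and `t100_recovery_s` is `NA` because
the slow ER decay has not returned to the noise band within the 60 s
recording.

A two-genotype cohort through the pipeline and the mixed-design test:

```r
co <- simulateCohort(nLarvae = 8, frequencies = c(20, 50), seed = 7)
fit <- multiGroupTest(data.frame(value = co$max_dff, genotype = co$genotype,
                                 frequency = co$frequency,
                                 larva_id = co$larva_id))
fit$effects
#>                 term statistic df1 df2      p_value
#> 1           genotype  78.39177   1  14 4.126073e-07
#> 2          frequency 469.64413   1  14 3.613389e-12
#> 3 genotype:frequency  62.07431   1  14 1.635221e-06

norm <- normalizeToControl(co$max_dff[co$frequency == 50],
                           co$genotype[co$frequency == 50], "WT")
mean(norm[co$genotype[co$frequency == 50] == "mutant"])
#> [1] 0.479
```

The simulated mutant halves evoked amplitudes (`genotypeScale = 0.5`);
the control-normalized mutant mean lands near 0.5 and the genotype main
effect is detected by the repeated-measures analysis.

A ready-made pipeline driver (`runPipeline()`, YAML-configurable) and a
thin command-line wrapper (`inst/scripts/nmjca.R` with `run`,
`fixtures` and `simulate` subcommands) orchestrate the stages and
persist every intermediate as CSV/TIFF plus a report.

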