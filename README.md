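# punctasim

Simulation and quantification of single-molecule FISH puncta in sensory
neurons.

## What it is for

RNAscope-style in situ hybridization shows individual mRNA transcripts as
fluorescent puncta. Studies of acid-sensing ion channel (ASIC) subunit
expression in mouse dorsal root ganglion (DRG) neurons quantify these
images per neuron: a cell is called positive when it shows ≥ 3 puncta, its
expression level is the background-corrected mean intensity in a circular
ROI, somata are sized and classed, and populations are compared across
markers (NF200 / CGRP / IB4), lumbar segments (L4 / L5) and nerve-injury
conditions (sham / cuff). None of those steps can be validated on real
tissue, where ground truth is unknown. `punctasim` rebuilds the whole
pipeline on synthetic data that *carries* its ground truth, so every stage
is checked by parameter recovery.

The package provides:

* **Population simulator** — neurons with marker class, soma area,
  per-probe expression (independent Bernoulli, or a joint 8-category
  multinomial over ASIC1a/ASIC2b/ASIC3 combinations), per-cell puncta
  counts, and declarative nerve-injury effects
  (`sample_population()`, `apply_condition_effects()`).
* **Image simulator** — point emitters with Poisson counts, uniform in a
  25 µm circular ROI, convolved with a Gaussian PSF
  (`PSF(x,y) = I₀·e^(−2(x²+y²)/ω₀²)`, ω₀ = 300 nm at 200 nm pixels),
  scaled so one punctum integrates to ε·π·(ω₀/px)² ≈ 706.9 i.u. and peaks
  at 2ε, plus Gaussian noise (`place_emitters()`, `psf_render()`,
  `add_noise()`, `render_section()`).
* **Spot detector** — thresholded strict local maxima (default 6 i.u.)
  with greedy minimum-separation suppression at ω₀, locked against a
  brute-force oracle (`detect_peaks()`, `saturation_experiment()`).
* **Quantification** — the ≥ 3-puncta rule, circular-ROI intensity with
  background subtraction, soma areas and the <650 / 650–900 / >900 µm²
  size classes, co-expression tables, per-marker percentages
  (`quantify_population()`, `coexpression_table()`,
  `marker_percentage_table()`).
* **Statistics** — scaled-Gaussian fits to 100 µm²-binned size
  histograms, the extra sum-of-squares F-test
  (F = ((SS_c−SS_s)/(df_c−df_s))/(SS_s/df_s)), empirical cumulative
  curves, pooled-variance unpaired t-tests on per-DRG percentages, and
  one-way ANOVA + Tukey on per-cell intensities
  (`fit_size_distribution()`, `extra_ss_f_test()`,
  `compare_proportions()`, `compare_intensities()`).

See the vignette (`vignettes/puncta-quantification.Rmd`) for the model,
its assumptions and the design decisions.

## Worked example

Simulate 300 neurons in multiplex mode, run the full
render–detect–call pipeline, and tabulate co-expression:

```r
library(punctasim)
params <- population_params(mode = "multinomial")
pop <- sample_population(params, 300, seed = 1)
q <- quantify_population(pop, sim_config(seed = 1), quant_config(), seed = 1)
coexpression_table(q)
#>           combination count    fraction
#> 1                none    66 0.220000000
#> 2              ASIC1a     3 0.010000000
#> 3              ASIC2b    45 0.150000000
#> 4               ASIC3    35 0.116666667
#> 5       ASIC1a+ASIC2b     1 0.003333333
#> 6        ASIC1a+ASIC3    71 0.236666667
#> 7        ASIC2b+ASIC3    58 0.193333333
#> 8 ASIC1a+ASIC2b+ASIC3    21 0.070000000
```

The recovered fractions sit within sampling error of the generating
probabilities (none 0.21, ASIC2b-only 0.15, ASIC3-only 0.14, triple 0.10,
…): at n = 300 the binomial SE of the triple-positive fraction is ~0.017,
so the observed 0.070 is within 2 SE of 0.10. The calls themselves are
essentially error-free at default noise — here every ASIC3 call matches
its ground truth.

The counting-saturation experiment reproduces why intensity, not puncta
number, must be used at high transcript density:

```r
saturation_experiment(sim_config(), densities = c(0.01, 0.31, 3.1),
                      reps = 20, seed = 1)
#>   density mean_true_n mean_detected_n detected_true_ratio mean_total_intensity
#> 1    0.01        5.05            5.05           1.0000000             3547.168
#> 2    0.31      156.50          147.75           0.9440895           110703.079
#> 3    3.10     1522.85          820.30           0.5386611          1076412.910
```

Detected counts fall to 54 % of truth at 3.1 puncta/µm², while total
intensity stays exactly linear in the true count (slope ≈ 706.9 i.u. per
punctum, the single-punctum integral).

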