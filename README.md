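# cooid — vocal individuality analysis for harmonic contact calls

`cooid` quantifies how much information about caller identity is carried by
short, harmonic-rich contact calls ("coo" calls), the call type by which
forest-living social primates such as golden snub-nosed monkeys
(*Rhinopithecus roxellana*) keep contact when out of sight. It is aimed at
bioacousticians who have per-call WAV recordings labelled by caller (or
want to simulate them) and need the standard individuality workflow,
end to end and reproducibly.

The package implements:

* **Feature extraction** — the 14 standard parameters per call: duration;
  mean/SD/min/max/range/start/end fundamental frequency from a
  cross-correlation pitch tracker (10-ms frames, 75–1200 Hz); mean
  harmonics-to-noise ratio, HNR = 10·log10(r/(1−r)) dB from the
  normalized correlation peak r; formants F1–F4 by Burg linear prediction
  (order 10, 8 kHz ceiling); and formant dispersion by the zero-intercept
  uniform-tube fit ΔF = Σ F·x / Σ x², x = (2k−1)/2, so that
  ΔF = c/(2L) for tract length L.
* **Individuality statistics** — small-sample-corrected coefficients of
  variation CV = 100·(1 + 1/4n)·SD/x̄ within and between individuals, and
  the potential for individual identity coding PIC = CV_b / mean CV_w
  (PIC > 1 ⇔ a parameter varies more between than within callers);
  Kruskal–Wallis screening per parameter with Bonferroni-adjusted pairwise
  Mann–Whitney tests.
* **Discrimination** — standardized PCA (eigenvalue > 0.6 retention,
  varimax rotation, regression-method scores), Kolmogorov–Smirnov normality
  report, linear DFA with observed-group-size priors, resubstitution and
  leave-one-out confusion matrices, and a one-sided exact binomial test of
  the cross-validated accuracy against the 100/k % chance level.
* **A source-filter synthesizer** — labelled populations of coo-like calls
  (pulse-train source with −12 dB/oct tilt, resonator-cascade tract,
  aspiration noise) with explicit control of between- vs within-individual
  variation, so the whole pipeline is testable without recordings.

See the methods vignette (`vignettes/cooid-methods.Rmd`) for the model
details and design decisions.

## Worked example

```r
library(cooid)

pop <- make_fixture("paper_like", seed = 1)   # 7 callers, 162 calls
res <- run_pipeline("reports", population = pop)
#> synthesizes audio, extracts features, writes features.csv,
#> table1.csv (CV/PIC), table2.csv (screening), table3.csv (confusion),
#> pca_summary.csv, dfa_summary.json, run.log

head(res$pic_report, 3)
#>   parameter mean_cv_w      cv_b      pic
#> 1  duration 15.181398 18.705346 1.232123
#> 2   mean_f0  5.352663  8.668514 1.619477
#> 3     sd_f0 67.592736 81.607569 1.207342

round(c(res$dfa_result$accuracy_resub, res$dfa_result$accuracy_loocv,
        res$dfa_result$chance_pct), 1)
#> [1] 88.3 84.6 14.3
```

All 14 parameters come out with PIC > 1 (the generator's default
`separation = 1` encodes caller identity in every parameter), the DFA
retains 6 components carrying 92.8% of the variance, and leave-one-out
classification assigns 84.6% of calls to the right caller against a 14.3%
chance level (binomial p ≪ 0.001). Setting `separation = 0` produces a null
population: PIC ≈ 1 everywhere and chance-level classification.

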