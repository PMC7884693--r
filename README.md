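# photoreca

Deep-learning CXR classifiers trained on clean digital radiographs fail
quietly when their input is a *smartphone photograph* of a radiograph
displayed on a monitor — the everyday artifact of clinical
teleconsultation, where a resident photographs the screen and sends the
image to a colleague. `photoreca` implements the recalibration remedy for
that domain shift, for researchers studying capture-robust medical image
classifiers:

1. an eight-operator, fully seeded **photographic degradation simulator**
   (Gaussian noise, saturation tint, overexposure, contrast change, motion
   blur, moiré synthesised by Radon/inverse-Radon round trips, Poisson shot
   noise, JPEG compression);
2. **calibration** of its ten free hyperparameters against a small set of
   reference photographs, with two similarity objectives — complex-wavelet
   structural similarity (CW-SSIM) and the Bhattacharyya distance between
   intensity histograms;
3. the **evaluation statistics** used for such studies: one-vs-all AUROC
   with bootstrap confidence intervals, Welch's t-test on bootstrap
   samples, ICC(A,1) with McGraw–Wong intervals, and averaged-AUROC table
   aggregation;
4. a **synthetic pseudo-CXR generator** with planted, exactly-labeled
   findings and a monitor-capture simulator with hidden ground truth, so
   the entire loop runs end to end with no downloads; and
5. a four-model **experiment harness** (ORIG / RECA / TRNS / PHOT against a
   clean-image reference) reporting the *recovery fraction*

   ```
   recovery = (AUROC_RECA − AUROC_ORIG) / (AUROC_REF − AUROC_ORIG)
   ```

   — the share of the photograph-induced performance loss that
   recalibration wins back.

The core model: a capture is `photo = JPEG(Poisson(Moire(Blur(Contrast(
Overexpose(Tint(Gauss(monitor(x)))))))))` with every stochastic element
drawn from one seeded stream, so the whole pipeline is a pure function of
`(image, config)`. Calibration searches `config` so that
`degrade(clean set)` maximizes CW-SSIM (or minimizes Bhattacharyya
distance) against real photographs; retraining on the calibrated
degradations re-aligns the classifier with the photographic domain.

## Worked example

```r
library(photoreca)

# 1. synthetic "study": clean pseudo-CXRs + photographs with hidden truth
spec  <- synthetic_spec(1, side = 64, seed = 101)
truth <- capture_truth(degradation_config(seed = 201), seed = 301)

# 2. run the four-model experiment (generation, capture simulation,
#    calibration on the photograph budget, training, evaluation)
report <- run_recalibration_experiment(spec, truth,
                                       n_train = 800, n_test = 400,
                                       n_boot = 100, seed = 1)
glance(report)
```

```
#> # A tibble: 1 x 9
#>   mean_ORIG mean_PHOT mean_RECA mean_REF mean_TRNS mean_recovery n_train n_test  seed
#>       <dbl>     <dbl>     <dbl>    <dbl>     <dbl>         <dbl>   <int>  <int> <int>
#> 1     0.705     0.821     0.933    0.994     0.635         0.824     800    400     1
```

Reading the numbers: the clean-trained model (ORIG) drops from an averaged
AUROC of 0.99 on clean test images (REF) to 0.70 on simulated photographs
of the same images — the domain shift. The recalibrated model (RECA),
trained only on clean images passed through the *calibrated* simulator,
scores 0.93 on those photographs: a mean recovery fraction of 0.82 of the
lost performance, without ever training on a real photograph beyond the
small calibration budget. `report$recovery` holds the per-finding
fractions, `tidy(report)` the per-finding AUROCs with bootstrap CIs, and
`autoplot(report)` plots them.

The pieces compose individually as well:

```r
img    <- generate_pseudo_cxr(spec, 1)$image
photo  <- simulate_capture(img, truth, seed = 7)
cw_ssim(img, photo)                         # e.g. 0.87 — degraded, related
cfg    <- calibrate(list(img), list(photo),
                    metric = "bhattacharyya", strategy = "similarity")
```

A command-line interface mirrors the R API for shell pipelines
(`inst/exec/photoreca`): subcommands `simulate`, `augment`, `similarity`,
`calibrate`, `evaluate`, `experiment`, each writing a JSON run manifest.

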