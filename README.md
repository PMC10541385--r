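# ctperf

CT perfusion (CTP) analysis for acute ischemic stroke, with a convolutional
curve-correction network for the arterial input function (AIF).

## The problem

CTP estimates, voxel by voxel, how much blood flows through brain tissue
during the passage of a contrast bolus. The tissue concentration curve
C(t) is modelled as the convolution of the arterial input function
Ca(t) with a flow-scaled residue function:

    C(t) = Ca(t) ⊛ R(t)
    CBF  = scale · max R(t)        (scale = 100·60 for mL/100 g/min)
    Tmax = argmax R(t)             (s)

Deconvolving C with Ca yields R; thresholding the resulting maps gives the
irreversibly infarcted **core** (relative CBF < 30% of a normal-tissue
reference) and the salvageable **penumbra** (Tmax > 6 s) — the volumes
that drive thrombectomy decisions.

Measured AIFs, however, carry a drifting baseline, amplitude errors in the
first passage and irregular recirculation. Because the AIF is the
deconvolution kernel for *every* voxel, these distortions corrupt whole
maps and can erase a real infarct core from the report. The remedy
implemented here: fit the bolus first passage with the gamma-variate
function

    C(t) = K (t − AT)^α exp(−(t − AT)/β),   t > AT

and train a small 1D CNN (conv(k=2) → conv(k=2) → average pooling →
flatten → dense(36) → softmax output, RMSprop, lr 0.001, batch 32) to map
a raw, spline-interpolated 500-point AIF directly to its gamma-fitted
counterpart. The softmax output is read as a normalised curve shape and
rescaled by the input's first-pass area.

Because no patient data ship with the package, everything is validated on
a seeded digital perfusion phantom with known ground-truth CBF, delay and
lesion geometry, plus synthetic NIHSS/ASPECTS severity scores that grow
with the true lesion volumes.

## Who this is for

Researchers developing or auditing perfusion post-processing: every stage
(AIF selection by recursive clustering, gamma fitting, block-circulant
SVD deconvolution with oscillation-index regularisation, thresholded
volumetry, agreement statistics) is an exported, unit-tested function.

## Worked example

Phantom → AIF selection → deconvolution → lesion volumes:

```r
library(ctperf)
res <- run_pipeline(pipeline_config(seed = 1), "without_cnn_aif")
print(res$lesions)
#> <lesion_result> reference CBF 41.8 mL/100g/min
#>        label volume_mL
#>    CBF < 20%       1.7
#>    CBF < 30%      11.4
#>    CBF < 38%      13.4
#>   Tmax > 4 s      69.8
#>   Tmax > 6 s      69.8
#>   Tmax > 8 s      69.8
#>  Tmax > 10 s      33.6
```

The phantom's true core is 13.5 mL and its true penumbra 69.84 mL: with a
clean measured AIF the pipeline lands on both (core 11.4 mL at the primary
CBF < 30% threshold, penumbra 69.8 mL at Tmax > 6 s).

Training the correction network and rescuing a severely distorted case:

```r
bank  <- make_curve_bank(n_datasets = 128, n_aifs = 3, seed = 10)
pairs <- augment_pairs(bank$pairs, seed = 11)          # 384 -> 1152
model <- train_cnn(build_cnn(cnn_config(seed = 42)), pairs, epochs = 50)
print(model)
#> <aif_cnn> input 500, conv 8/16 (k=2), pool 2, dense 36 -> 500; trained; 162256 parameters

sev <- distortion_params(baseline_slope = 0.05, baseline_noise_sd = 0.2,
                         peak_attenuation = 0.35, recirc_amplitude = 0.5)
cfg <- pipeline_config(phantom = phantom_config(aif_distortion = sev),
                       seed = 101, model = model)
res <- compare_aif_modes(cfg)
core <- function(r) r$volumes_mL$volume_mL[r$volumes_mL$label == "CBF < 30%"]
cat(sprintf("true core %.1f mL | with CNN AIF %.1f mL | without %.1f mL\n",
            res$with_cnn_aif$true_core_mL, core(res$with_cnn_aif),
            core(res$without_cnn_aif)))
#> true core 13.5 mL | with CNN AIF 12.2 mL | without 1023.0 mL
```

With the raw distorted AIF the reference collapses and the thresholded
"core" swallows the brain; the CNN-corrected AIF restores a 12.2 mL
estimate against a 13.5 mL truth.

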