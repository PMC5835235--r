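# eegclean

Fully automated artifact removal and data-quality reporting for continuous
multichannel EEG with high artifact load — the regime of developmental and
clinical resting-state recordings, where files are short, blinks and muscle
activity contaminate most of the record, dedicated eye channels are
unavailable, and manual cleaning neither scales nor reproduces. The package
is aimed at researchers who need every file processed the same way, with a
per-file quality report instead of per-file judgement calls.

## What it does

Each recording passes through a fixed chain:

1. **Zero-phase FIR filtering** — 1 Hz high-pass, or a 1–249 Hz band-pass
   for sampling rates ≥ 500 Hz.
2. **Channel-subset selection** against the ICA sample budget: a reliable
   decomposition of *C* channels needs at least **30·C²** samples, so
   short high-density recordings are processed on a user-chosen subset
   that must include the 19 mapped 10–20 electrodes.
3. **Line-noise removal** by multitaper sinusoid regression (Slepian
   tapers, NW = 4): per 4-s window (1-s step) the exact line frequency is
   located within ±2 Hz of the target by maximizing the Thomson
   F-statistic, and the fitted sinusoid is subtracted where the regression
   coefficient is significant at p < 0.01 — no notch, so neighbouring EEG
   frequencies are untouched.
4. **Bad-channel detection**, run twice: a channel is rejected when the
   normed joint probability of its average log power (1–125 Hz) falls more
   than 3 standard deviations from the mean.
5. **Wavelet-enhanced ICA (W-ICA)**: extended Infomax components are
   stationary-wavelet transformed (Coiflet-5) and soft-thresholded with
   the robust universal threshold

   *T* = (median|D| / 0.6745) · √(2 ln N),

   where D are the finest detail coefficients and N the component length;
   the content surviving the threshold is the artifact stream and is
   subtracted in channel space. Nothing is deleted: cleaned + artifact
   equals the input sample-exactly.
6. **ICA with automated component rejection**: each component is scored on
   six temporal/spectral/spatial features (local skewness, log alpha
   power, 1/f fit slope λ and fit error, scalp-map range, current-density
   norm) and rejected when its artifact probability exceeds 0.5.
7. Optional **segmentation**, then either amplitude (±40 µV default) plus
   joint-probability segment rejection, or per-segment bad-channel repair.
8. **Spherical-spline interpolation** (stiffness m = 4, Legendre order
   ≤ 7) of the bad channels, restoring the full channel set.
9. **Re-referencing** (average or channel set), and one row of quality
   metrics per file (good-channel %, interpolated IDs, ICs rejected,
   % variance kept, artifact-probability statistics of kept components).

A seeded synthetic EEG generator with exact ground truth (blinks, EMG
bursts, line noise, drift, dead/noisy channels) makes every stage testable
without any external data. See the methods vignette
(`vignettes/methods.Rmd`) for models, parameter rationale and limitations.

## Worked example

```r
library(eegclean)

# a heavily contaminated 19-channel, 50-s resting recording with a dead
# electrode, plus exact ground truth
montage <- load_montage("sphere128")
spec <- synth_spec(n_channels = 19, duration_sec = 50, seed = 95,
                   flat_channels = montage$ten_twenty[["T5"]])
synth <- generate_recording(spec)
print(synth$recording)
#> <eeg_recording> 19 channels x 12500 samples @ 250 Hz (50.00 s, rest)

ica_sample_budget(19, n_samples(synth$recording), synth$recording$sample_rate)
#> ICA sample budget: C = 19 needs 10830 samples; available 12500 (sufficient); 43.32 s at the given rate

cfg <- pipeline_config(segment_mode = "reject", seed = 4)
res <- process_recording(synth$recording, cfg, filename = "demo")
res$report
#> Number_good_channels_selected                "17"
#> Interpolated_channel_IDs                     "E83 E84"
#> Number_epochs_post_epoch_rejection           "22"
#> Percent_ICs_rejected                         "0"
#> Percent_variance_kept_of_post_waveleted_data "100"
#> Median_artifact_probability_of_kept_ICs      "0.2536976"
```

The planted dead electrode (`E84`, the mapped T5) is caught by the
bad-channel pass and interpolated, together with `E83` — the lateral
channel where this seed's EMG bursts concentrate, so its power is
genuinely outlying. Of the 25 two-second segments, 22 survive rejection.
Here W-ICA absorbed the blink and EMG energy, so the second ICA found no
component above the 0.5 rejection threshold and 100% of post-wavelet
variance is kept; the overall effect is visible in amplitude:

```r
sqrt(mean(synth$recording$data^2))   # raw:       52.3 uV RMS
sqrt(mean(res$recording$data^2))     # processed:  9.4 uV RMS
```

Batches run through `run_pipeline(cfg, files)` (native or EDF inputs),
which writes per-file outputs, optional stage intermediates, a
`processing_report.csv`, and isolates per-file failures.
`summarize_cohort(report)` tabulates mean/SD/quartiles of every metric. A
thin command-line wrapper ships in `inst/cli/eegclean.R`
(`run`, `summarize`, `synth` subcommands).

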