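# lungcycler

Automatic respiratory-cycle segmentation and classification of common lung
sounds from single-channel auscultation audio.

Auscultation — listening to the lungs through a (digital) stethoscope —
remains a first-line diagnostic for chronic respiratory disease, but
reliably telling apart normal breath sounds, rhonchi and fine/coarse
crackles takes expert ears. An automated pipeline needs three pieces, and
this package implements all of them for 44.1 kHz mono recordings:

1. **Cycle detection.** Recordings contain 3–7 respiratory cycles of
   individually varying length. A spectral-energy envelope in the
   80–1000 Hz band (10 ms Hamming frames) is robustly smoothed
   (Whittaker-type penalized least squares with bisquare reweighting), and
   cycle boundaries are chosen among prominent, deep envelope minima by
   dynamic time warping: the segments between candidate boundaries are
   amplitude-normalized and a segment whose DTW distance to the medoid
   pattern exceeds θ·median is merged away. Kept cycles must last between
   1.25 s and 5.5 s; everything else is excluded as an outlier, with a
   reason.
2. **Time-frequency images.** Each signal is rendered as a spectrogram
   (128/64/1024 STFT), Mel-spectrogram (128 bands, 62.5 Hz–15 kHz),
   gammatonegram (64 ERB-spaced gammatone channels from 50 Hz, 25 ms/10 ms
   integration, time-domain filter bank) or bump-wavelet scalogram, then
   resized to a 256×256×3 model input in [0, 1].
3. **Classification.** Three configurations over a frozen convolutional
   backbone: a trained softmax head (`cnn`), a CNN–BiLSTM hybrid that
   reshapes the 7×7-style feature map into a 9×64 sequence
   (`cnn_lstm`: BiLSTM-256 → FC-512 with dropout 0.5 → softmax), and a
   linear SVM on pooled features (`cnn_svm`). Evaluation follows a
   stratified 80/10/10 split at the cycle level, repeated 10 times,
   reporting mean ± standard deviation of test accuracy plus class-wise
   precision/recall/F1 (precision = TP/(TP+FP), recall = TP/(TP+FN),
   F1 = 2PR/(P+R)) and a confusion matrix from the repeat closest to the
   mean.

Clinical recordings are rarely shareable, so the package also ships a
synthetic lung-sound generator (`generate_corpus()`) producing labelled
recordings with exact ground-truth boundaries, per-class acoustics
(band-limited breath noise, ~150 Hz amplitude-modulated rhonchi tone,
5 ms/15 ms crackle transients) and controllable SNR — every stage of the
pipeline is testable against known truth. The bundled backbone is a small
deterministic convolutional feature extractor (fixed analytic kernels,
parallel max/mean pooling), so nothing needs to be downloaded; pretrained
backbones can be plugged in behind the same `backbone_spec()` contract.

## Worked example

```r
library(lungcycler)

# a synthetic 5-cycle fine-crackle recording at 15 dB SNR
rec <- generate_recording("fine_crackle", n_cycles = 5, snr_db = 15, seed = 7)
rec
#> <synthetic_recording: fine_crackle, 5 cycles, 12.95 s, SNR 15 dB>

seg <- segment_recording(rec$audio)
seg
#> <lung_segmentation: 5 cycles kept, 0 spans excluded>
#>   durations: 4.55, 2.69, 1.83, 1.76, 2.12 s
true_boundaries_s(rec)
#> [1]  4.47  7.16  9.01 10.72
```

All five cycles are recovered; the detected junctions (4.55, 7.24, 9.07,
10.83 s from the cumulative durations) each fall within about 0.1 s of
the ground truth. Featurization and the repeated-split
experiment (here 50 recordings per class and 10 repeats; ~3 minutes on one
core):

```r
corp   <- generate_corpus(50, seed = 42)           # 200 recordings, SNR 15 dB
feats  <- featurize_corpus(corp, representation = "gammatonegram")
report <- repeat_experiment(feats, kind = "cnn",
                            split = split_config(n_repeats = 10, seed = 1))
report
#> <eval_report: gammatonegram + cnn, 10 repeats>
#>   test accuracy: 97.0% +/- 3.5%
#>   class-wise (representative repeat 5):
#>     coarse_crackle  P=0.83 R=1.00 F1=0.91 (n=5)
#>     fine_crackle    P=1.00 R=1.00 F1=1.00 (n=5)
#>     normal          P=1.00 R=0.80 F1=0.89 (n=5)
#>     rhonchi         P=1.00 R=1.00 F1=1.00 (n=5)
```

The mean/std summarize test accuracy over the ten random partitions; the
class-wise table comes from the repeat whose accuracy is closest to the
mean. `report$confusion` holds the corresponding confusion matrix (rows =
true class, columns = predicted), whose rows sum to the per-class test
counts.

A thin command-line front end is installed under `inst/cli/lungcycler`:

```sh
Rscript inst/cli/lungcycler simulate --n-per-class 2 --snr-db 15 --seed 1 --out sim/
Rscript inst/cli/lungcycler segment sim/normal_001.wav --out seg/
Rscript inst/cli/lungcycler featurize sim/normal_001.wav --rep gamma --out img/
```

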