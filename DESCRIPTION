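Package: lungcycler
Title: Automatic Respiratory-Cycle Segmentation and Lung-Sound Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully automatic pipeline for single-channel lung-sound
    (auscultation) analysis. Detects respiratory cycles from 44.1 kHz audio
    via a band-energy envelope (80-1000 Hz), robust Whittaker smoothing and
    dynamic-time-warping pattern similarity, with physiological duration
    filtering (1.25-5.5 s). Computes four time-frequency representations
    (spectrogram, Mel-spectrogram, gammatonegram from a 64-channel ERB-spaced
    gammatone filter bank, and a bump-wavelet scalogram) and converts them to
    fixed 256x256x3 model inputs. Trains three classifier configurations
    (frozen convolutional backbone with a softmax head, a CNN-BiLSTM hybrid,
    and frozen features with a linear SVM) under a repeated stratified
    80/10/10 split protocol, reporting mean and standard deviation of test
    accuracy, class-wise precision/recall/F1 and confusion matrices. Includes
    a synthetic lung-sound generator (normal, rhonchi, fine and coarse
    crackle) with known cycle boundaries and configurable SNR so the whole
    pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    e1071,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
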