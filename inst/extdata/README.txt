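Reference fixtures (format validation and report arithmetic only)
=================================================================

reference_model_metrics.csv
    Published per-model accuracy / macro precision / recall / F1 of the six
    KOA-tuned classifiers and the six candidate stacking ensembles on the
    original (undeposited) mung-bean dataset. Used to exercise the
    reporting and relative-improvement arithmetic; the package makes no
    claim of reproducing these values from data.

reference_selected_wavenumbers.json
    The 44 Raman wavenumbers (cm^-1, out of 700 channels) reported as the
    optimal CARS subset for the original spectral dataset.

reference_selected_image_features.json
    The 15 image-feature names (out of 43) reported as the optimal CARS
    subset for the original image dataset.

These selections are data-dependent; synthetic runs are scored against the
synthetic generator's own recorded ground truth, never against these lists.
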