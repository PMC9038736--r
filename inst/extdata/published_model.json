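{
  "description": "Published 12-feature radiomics signature for predicting malignancy of vertebral compression fractures. Scores are linear combinations of standardized features; the training-cohort standardization parameters were not released.",
  "intercept": -0.176,
  "cutoff": 0.328,
  "standardization": "unspecified",
  "features": [
    {"id": "original__morphological__approximate_volume", "name": "Approximate volume", "family": "Morphological features", "beta": -0.483},
    {"id": "original__morphological__major_axis_length", "name": "Major axis length", "family": "Morphological features", "beta": -0.544},
    {"id": "original__local_intensity__global_intensity_peak", "name": "Global intensity peak", "family": "Local intensity features", "beta": 0.837},
    {"id": "original__statistics__minimum", "name": "Minimum gray level", "family": "Intensity-based statistical features", "beta": 0.745},
    {"id": "original__histogram__mean", "name": "Intensity histogram mean", "family": "Intensity histogram features", "beta": 0.730},
    {"id": "original__histogram__robust_mean_absolute_deviation", "name": "Intensity histogram robust mean absolute deviation", "family": "Intensity histogram features", "beta": 0.104},
    {"id": "original__glcm__joint_entropy", "name": "Joint entropy", "family": "Gray level co-occurrence matrix", "beta": -0.088},
    {"id": "original__glszm__small_zone_low_grey_level_emphasis", "name": "Small zone low gray level emphasis", "family": "Gray level size zone matrix", "beta": -0.994},
    {"id": "original__ngldm__high_dependence_emphasis", "name": "High dependence emphasis", "family": "Neighboring gray level dependence matrix", "beta": 0.329},
    {"id": "log_1__local_intensity__local_intensity_peak", "name": "Local intensity peak (LoG)", "family": "LoG local intensity features", "beta": -0.444},
    {"id": "log_1__statistics__p75", "name": "75th percentile (LoG)", "family": "LoG intensity-based statistical features", "beta": -0.105},
    {"id": "log_1__histogram__max_gradient", "name": "Maximum histogram gradient (LoG)", "family": "LoG filtered intensity histogram features", "beta": -0.051}
  ]
}
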