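{
  "2D": {
    "feature_names": [
      "EY",
      "OG"
    ],
    "weights": [
      15.01,
      -43.55
    ],
    "bias": 1.454,
    "name": "2D",
    "positive_label": "EC"
  },
  "3D": {
    "feature_names": [
      "EY",
      "LG",
      "OG"
    ],
    "weights": [
      41.52,
      -55.34,
      -46.79
    ],
    "bias": 3.263,
    "name": "3D",
    "positive_label": "EC"
  },
  "sRGB": {
    "feature_names": [
      "R",
      "G",
      "B"
    ],
    "weights": [
      83.41,
      -368.9,
      365.8
    ],
    "bias": -74.22,
    "name": "sRGB",
    "positive_label": "EC"
  }
}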