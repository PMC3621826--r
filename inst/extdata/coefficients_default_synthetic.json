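{
  "components": {
    "ptjc28": {
      "intercept": -80.3768119793898,
      "coefficients": {
        "TNFRI": 10.8940581118293,
        "VEGFA": 10.9848695878834,
        "VCAM1": 8.91194693673912,
        "YKL40": 3.86055808125549
      }
    },
    "psjc28": {
      "intercept": -44.5832602124079,
      "coefficients": {
        "IL6": 9.26494785410141,
        "SAA": 1.93336500019669,
        "TNFRI": 9.18814221697506,
        "VEGFA": 6.48173781381633
      }
    },
    "ppga": {
      "intercept": -28.6521255520779,
      "coefficients": {
        "TNFRI": 3.58464195305156,
        "VCAM1": 3.80355194381545,
        "IL6": 3.00572705469708,
        "VEGFA": 2.98591696341658,
        "SAA": 0.514303560960183
      }
    }
  },
  "shrinkage": [
    [0.483108842311623, 0.561221565933015],
    [0.435357023872383, 0.505748869154403]
  ],
  "combination": {
    "sqrt_iptjc": 0.56,
    "sqrt_isjc": 0.28,
    "log_crp": 0.36,
    "ppga": 0.14,
    "constant": 0.96
  },
  "scale": 10.53,
  "offset": 1,
  "bounds": [1, 100],
  "exponent": 0.1,
  "crp_unit": "mg/L",
  "metadata": {
    "provenance": "SYNTHETIC default: component sub-models and shrinkage matrix trained by train_cw_lasso() on the training-like synthetic preset (seed 20130413); combination weights are the DAS28-CRP(4) weights; scale/offset/bounds/exponent are the published constants.",
    "family": "cw-lasso",
    "seed": 20130413
  }
}
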