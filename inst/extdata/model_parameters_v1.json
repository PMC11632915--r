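{
  "version": "published-v1",
  "comment": "Published carbon-ion model constants and covariance. Dose units Gy, LET_d units keV/um. Ordering for the covariance block is (f1, m1, q1, f2).",
  "f1": 2.095070e-2,
  "m1": 5.955453e-1,
  "q1": 2.133918e-5,
  "f2": 2.230798e-2,
  "se": {
    "f1": 8.575542e-3,
    "m1": 4.089380e-1,
    "q1": 8.756112e-6,
    "f2": 3.479508e-3
  },
  "cov": {
    "f1_m1": 2.945233e-3,
    "f1_q1": 4.704403e-9,
    "f1_f2": 1.172688e-6,
    "q1_m1": -8.767703e-7,
    "m1_f2": -6.539078e-6,
    "q1_f2": 1.257442e-9
  }
}
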