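{
  "_comment": "Example literature-style radiobiology configuration; values are illustrative, not package defaults. alpha/beta 2.47 Gy suits late-responding normal tissue; 8.2 Gy is a common tumour value. Bi-exponential repair half-times and partition coefficient follow published Gamma Knife BED practice.",
  "alpha_beta_gy": 2.47,
  "t_half_fast_min": 11.4,
  "t_half_slow_min": 129.6,
  "partition_c": 0.98
}
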