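# Demonstration configuration: the XZP-5610 translation with the reference
# program constants. Synthetic studies are generated noise-free so the NCA
# and Ka stages recover the configured truths exactly.
drug:
  xzp5610: true
species:
  rat_bw: 0.245
  dog_bw: 7.21
  human_bw: 60
studies:
  noise_cv: 0
  bsv_cv: 0
  # v here is the oral V (L/kg) setting the terminal slope of the mean oral
  # profile, not the IV Vss
  rat: {cl: 1.9, v: 3.6, ka: 2.34, f: 0.147}
  dog: {cl: 0.2, v: 1.05, ka: 0.589, f: 0.574}
allometry:
  sss_exponent: 0.66
  aggregate_source: reference
dose:
  safety_factor: 10
  mabel_mg: 2
  mtd_mg: 3
  granularity: 0.05
  efficacy_heds_mg: [2.18, 2.46, 4.80]
pbpk:
  human_doses_mg: [0.15, 0.5, 1, 3]
  t_end_h: 48
  dt_h: 0.05
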