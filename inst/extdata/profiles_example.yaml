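# Example simulation configuration for `extremabeat simulate`.
# Any field omitted falls back to the built-in subject defaults; a missing
# phase or subject uses hd_profile() / nc_profile() entirely.
hd:
  rest:
    mean_rr: 0.9          # seconds per beat (~67 bpm)
    rr_sd: 0.04
    sbp_baseline: 121     # mmHg
    dbp_baseline: 75
    sv_baseline: 60       # ml
    tpr_baseline: 1.1     # MU; set to enable independent resistance dynamics
    duration: 300         # seconds
    seed: 11
    oscillations:
      map:                # common-mode pressure oscillation (sbp and dbp)
        - {frequency: 0.39, amplitude: 2.5}
      tpr:
        - {frequency: 0.41, amplitude: 0.009}
    noise_sd: {sbp: 0.1, dbp: 0.1, sv: 0.25, tpr: 0.0005}
nc:
  rest:
    mean_rr: 0.8
    rr_sd: 0.04
    sbp_baseline: 118
    dbp_baseline: 78
    sv_baseline: 80
    tpr_baseline: 1.0
    duration: 300
    seed: 12
    oscillations:
      map:
        - {frequency: 0.17, amplitude: 3.5}
      tpr:
        - {frequency: 0.39, amplitude: 0.055}
    noise_sd: {sbp: 0.1, dbp: 0.1, sv: 0.2, tpr: 0.0005}
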