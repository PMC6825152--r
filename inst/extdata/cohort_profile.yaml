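# Class parameter distributions for synthetic cohort generation.
# Each entry is a [low, high] range sampled uniformly and independently.
# Units: conductance densities S/cm^2, voltages mV, area cm^2.
# RS cells carry a substantial M-type conductance and a low Kv3.1 baseline;
# FS cells carry high Kv3.1 and little M-type conductance.
classes:
  RS:
    gbar:
      na_t: [0.14, 0.17]
      kdr: [0.003, 0.006]
      km: [0.0040, 0.0060]
      kv31: [0.005, 0.030]
    g_leak: [4.5e-4, 5.5e-4]
    e_leak: [-68, -66]
    area: [0.9e-5, 1.1e-5]
  FS:
    gbar:
      na_t: [0.15, 0.18]
      kdr: [0.003, 0.006]
      km: [0.0001, 0.0004]
      kv31: [1.2, 1.5]
    g_leak: [4.5e-4, 5.5e-4]
    e_leak: [-68, -66]
    area: [0.9e-5, 1.1e-5]
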