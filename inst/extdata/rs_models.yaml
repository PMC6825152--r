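# Reduced regular-spiking interneuron model configurations (somatic-scale
# single compartment). Units: conductance densities S/cm^2, capacitance
# uF/cm^2, area cm^2, voltages mV. Channel names reference the package
# channel registry. The kv31 value is the model's low-expression baseline;
# the conductance sweep raises it to 1.5 S/cm^2.
models:
  - name: rs_a
    cm: 1.0
    area: 1.0e-5
    g_leak: 5.0e-4
    e_leak: -67
    v_init: -70
    gbar:
      na_t: 0.150
      kdr: 0.004
      km: 0.0050
      kv31: 0.009
  - name: rs_b
    cm: 1.0
    area: 1.0e-5
    g_leak: 4.5e-4
    e_leak: -66
    v_init: -70
    gbar:
      na_t: 0.140
      kdr: 0.003
      km: 0.0045
      kv31: 0.020
  - name: rs_c
    cm: 1.0
    area: 1.0e-5
    g_leak: 5.5e-4
    e_leak: -68
    v_init: -70
    gbar:
      na_t: 0.160
      kdr: 0.006
      km: 0.0055
      kv31: 0.030
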