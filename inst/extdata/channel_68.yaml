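# Single-channel fixture with a 68% lesion and the sensor disk 1 cm
# distal: the geometry used for severity and sensor-position studies.
geometry:
  fixture: channel
  channel: {length: 4, diameter: 0.3, degree: 0.68,
            lesion_center: 1.5, lesion_length: 0.8}
  h: 0.1
outlets:
  kind: windkessel
simulation:
  dt: 0.005
  n_cycles: 5
experiment:
  kind: sweep
  direction: normal
  n_positions: 7
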