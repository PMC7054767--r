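# Packaged study configuration: synthetic two-lesion left coronary tree,
# Carreau rheology, Windkessel outlets, five cardiac cycles.
geometry:
  fixture: coronary_tree
  lesions: [1, 2]     # 1 = 68% (short terminal branch), 2 = 56% (longest)
  sensors: true
  h: 0.1              # element size, cm
fluid:
  rho: 1060           # kg/m^3
  model: carreau      # carreau | newtonian
  newtonian_mu: 0.0032
  carreau: {mu0: 0.0456, mu_inf: 0.0032, lambda: 10.03, n: 0.344}
forcing:
  Ip: 10              # cm/s
  I0: 10
  Ic: 10
  Tsys: 0.33          # s
  Tc: 0.8             # s
  pd: {Q0: 6, baseline: 2}   # downstream-pressure construction
outlets:
  kind: windkessel    # windkessel | free | mixed
  R: 0.95             # mmHg s/cm^3
  C: 1.06             # cm^3/mmHg
simulation:
  dt: 0.005           # s
  n_cycles: 5
  inlet_mode: dirichlet_poiseuille
  snapshots: false
ffr:
  aortic_arclength: 1.0   # cm from the inlet
  box_half_width: 0.05    # cm
experiment:
  kind: run
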