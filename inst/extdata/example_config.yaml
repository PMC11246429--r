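# Example end-to-end run configuration.
# Seeds are mandatory: every generated observable must be reproducible.
version: 1
seed: 42
generator:
  sequence:
    length: 200
    first_residue_number: 401
    placements:
      - {pos: 450, seq: DLF}
      - {pos: 520, seq: DPF}
  titration:
    a_total: 100          # uM observed protein
    partner_id: partner
    points:
      - {label: "0%",   b: "0%"}
      - {label: "50%",  b: "50%"}
      - {label: "100%", b: "100%"}
      - {label: "150%", b: "150%"}
    kd_sites: {"450": 177, "451": 177, "452": 177,
               "520": 294, "521": 294, "522": 294}
    r_free: 3             # s-1 free-state R1rho
    r_bound: 30           # s-1 bound-state R1rho (measured on the partner)
    noise_sd: 0.02        # relative rate noise
  dispersion:
    dw_map: {"450": 2.5, "451": 3.1, "452": 1.4}
    k_ex: 662             # s-1
    p_b: 0.089
    fields: [600, 850]    # MHz
    noise_sd: 0.5         # s-1 absolute
  itc:
    n: 1
    kd: 5.1               # uM
    dh: -10               # kcal/mol
    cell_conc: 30
    syringe_conc: 300
    cell_volume: 200
    n_injections: 19
    injection_volume: 2
    noise_sd: 0.01
  shifts:
    helix_spec:
      - {range: [550, 570], population: 0.3}
    noise_sd: 0.02
stages:
  relaxation: {r_bound: 30, n_mc: 100}
  cpmg: {a_total: 100, b_total: 10}
  itc: {}
  conformation: {window: 5}
  motifs: {min_prominence: 2}
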