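# Final population model of high-dose methotrexate disposition.
# Fixed effects are the final estimates; omega values are log-scale SDs of
# the inter-individual variability on CL and Vc (see the methods vignette
# for how these defaults were chosen).
fixed_effects:
  theta_cl: 12.88      # L/h
  theta_vc: 72.04      # L
  beta_egfr_cl: 0.23
  beta_bw_cl: 0.39
  beta_tbil_cl: -0.05
  beta_alb_cl: -0.18
  beta_blm_cl: 0.08
  beta_bw_vc: 0.31
  q_fixed: 1.08        # L/h
  vp_fixed: 94.94      # L
reference_medians:
  egfr: 102.2          # mL/min/1.73 m2
  bw: 47.0             # kg
  tbil: 15.3           # umol/L
  alb: 40.9            # g/L
omega:
  cl: 0.30
  vc: 0.32
error:
  kind: proportional
  sigma_prop: 0.37
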