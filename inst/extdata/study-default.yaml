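# Default study configuration: the paper-calibrated kinetics, both rig
# presets, 1% absolute HPLC noise with a 2% blank-fault rate, and the
# standard campaign budgets (25 single-step, 18 telescoped).
kinetics: paper
rig_osat: osat
rig_telescoped: telescoped
noise:
  sigma_abs: 0.01
  p_fault: 0.02
campaign:
  budget_osat: 25
  budget_telescoped: 18
  monitoring_interval: 4
  plateau_window: 5
  plateau_delta: 0.005
  hours_per_experiment: 2
seed: 1
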