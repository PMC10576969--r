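# Placeholder thresholds for the last three flow-chart steps.
# Values are midpoints of the calibration Yes/No group means (individuals/m2,
# tau_S in taxa). They are starting points for regional refinement, not dogma;
# override any field from your own calibration run.
tau_S: 3
tau_d:
  Alcyonacea: 0.88
  Scleractinia: 2.035
  Porifera: 0.935
tau_D: 4.16
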