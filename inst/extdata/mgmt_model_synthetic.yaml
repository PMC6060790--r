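# Synthetic two-probe MGMT logistic model for testing and demonstration.
# The coefficients are NOT clinically validated; load the published model
# parameters from their source for diagnostic use.
probes:
  - cg_mgmt_A
  - cg_mgmt_B
intercept: 4.3
weights:
  - 0.53
  - 0.93
cutoff_low: 0.2
cutoff_high: 0.6
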