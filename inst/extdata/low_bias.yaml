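# Cells with low motor bias (reduced receptor and CheY content,
# strongly CCW-biased motor)
N_tot: 4200
Y_tot: 2
motor:
  mode: linearized
  k_plus_star: 0.015
  k_minus_star: 4.75
  dkplus_dYp: 4.75
  dkminus_dYp: -5.5
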