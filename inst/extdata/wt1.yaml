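# Wild-type parameter set (defaults written out explicitly)
A_tot: 5.0      # uM
B_tot: 0.28     # uM
R_tot: 0.16     # uM
Y_tot: 9.7      # uM
V_cell: 1.4     # fl
N_tot: 7027
k_2: 1000.0      # 1/s
k_A: 10         # 1/s
k_y: 100        # 1/uM/s
k_b: 15         # 1/uM/s
k_minus_y: 5    # 1/s
k_minus_b: 1.35 # 1/s
gamma_R: 0.0061 # 1/s
gamma_B: 3.14   # 1/uM^2/s
D: 1000.0        # um^2/s (ligand diffusion; not a measured pathway value)
s_R: 1          # nm
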