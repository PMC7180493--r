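# Method constants of the modified Lydersen-Joback-Reid chain.
# Units: temperatures K, pressures bar, volumes cm3/mol.
tb_offset_k: 198.2     # Tb = offset + sum(n * dTbM)
tc_a: 0.5703           # Tc = Tb / (a + b*S - S^2), S = sum(n * dTM)
tc_b: 1.0121
pc_c: 0.2573           # Pc = Mw / (c + sum(n * dPM))^2
vc_e_cm3_mol: 6.75     # Vc = e + sum(n * dVM)
pb_bar: 1.01325        # vapour pressure at the normal boiling point
r_cm3_bar_mol_k: 83.14 # gas constant for the mixture Pc closure
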