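# Literature Watson-Crick nearest-neighbor helix parameters (two-state
# analysis of 90 duplexes, 1 M NaCl). dH in kcal/mol, dS in cal/(mol K).
# Disordered-loop features are not part of the two-state model and are
# filled in code (see two_state_loop_preset()).
feature,dH_kcal_mol,dS_cal_mol_K
AA/UU,-6.82,-19.0
AU/UA,-9.38,-26.7
UA/AU,-7.69,-20.5
CU/GA,-10.48,-27.1
CA/GU,-10.44,-26.9
GU/CA,-11.40,-29.5
GA/CU,-12.44,-32.5
CG/GC,-10.64,-26.7
GG/CC,-13.39,-32.7
GC/CG,-14.88,-36.9
initiation,3.61,-1.5
terminal_AU,3.72,10.5
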