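# Printed torsional-scan results for the C4-C6-C5-C3 dihedral (raw scan energies unpublished; barriers kJ/mol, angles degrees as stated)
id,barrier_kj_mol,max_angle_deg,min_angle_deg
BZL,16.3175,40,130
DMB,8.2860,30,140
DFB,17.4132,40,140
DCB,16.4048,40,140
DBB,8.3755,30,130
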