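# Atom-contribution table for the additive AlogP estimate.
# Classes are assigned by element and bonding environment; values are in
# log-units per atom. Edit and pass through alogp_table() to customize.
class	contribution
C_ali	0.1441
C_het	-0.2035
C_aro	0.1581
N_amine	-1.0190
N_amide	-0.6027
N_aro	-0.3239
N_other	-0.5188
O_hydroxyl	-0.2893
O_carbonyl	-0.1526
O_ether	-0.2893
O_aro	0.1552
O_anion	-0.3339
S_any	0.6482
P_any	0.8612
F_any	0.4202
Cl_any	0.6895
Br_any	0.8456
I_any	0.8857
H_on_C	0.1230
H_on_het	-0.2677
other	0.0
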