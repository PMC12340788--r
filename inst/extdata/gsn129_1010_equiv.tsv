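label	channel
Fz	E11
F3	E24
F4	E124
C3	E36
C4	E104
T7	E45
T8	E108
P3	E52
P4	E92
Pz	E62
PO7	E65
PO8	E96
O1	E70
O2	E83
Oz	E75
Cz	Cz
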