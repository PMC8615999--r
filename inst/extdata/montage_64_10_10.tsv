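# 64-channel 10-10 montage, approximate top-down projection (synthetic coordinates; head radius 1)
Fp1	-0.31	0.95
Fpz	0	0.95
Fp2	0.31	0.95
AF7	-0.62	0.77
AF3	-0.31	0.77
AFz	0	0.77
AF4	0.31	0.77
AF8	0.62	0.77
F7	-0.83	0.55
F5	-0.622	0.55
F3	-0.415	0.55
F1	-0.208	0.55
Fz	0	0.55
F2	0.207	0.55
F4	0.415	0.55
F6	0.622	0.55
F8	0.83	0.55
FT7	-0.96	0.28
FC5	-0.72	0.28
FC3	-0.48	0.28
FC1	-0.24	0.28
FCz	0	0.28
FC2	0.24	0.28
FC4	0.48	0.28
FC6	0.72	0.28
FT8	0.96	0.28
T7	-1	0
C5	-0.75	0
C3	-0.5	0
C1	-0.25	0
Cz	0	0
C2	0.25	0
C4	0.5	0
C6	0.75	0
T8	1	0
TP7	-0.96	-0.28
CP5	-0.72	-0.28
CP3	-0.48	-0.28
CP1	-0.24	-0.28
CPz	0	-0.28
CP2	0.24	-0.28
CP4	0.48	-0.28
CP6	0.72	-0.28
TP8	0.96	-0.28
P7	-0.83	-0.55
P5	-0.622	-0.55
P3	-0.415	-0.55
P1	-0.208	-0.55
Pz	0	-0.55
P2	0.207	-0.55
P4	0.415	-0.55
P6	0.622	-0.55
P8	0.83	-0.55
PO7	-0.62	-0.77
PO3	-0.31	-0.77
POz	0	-0.77
PO4	0.31	-0.77
PO8	0.62	-0.77
O1	-0.31	-0.95
Oz	0	-0.95
O2	0.31	-0.95
P9	-1	-0.62
P10	1	-0.62
Iz	0	-1.05
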