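name	x	y	z	location
FP1	-0.309017	0.951057	0	1
FPZ	0	1	0	0
FP2	0.309017	0.951057	0	-1
AF3	-0.314415	0.926952	0.204703	1
AF4	0.314415	0.926952	0.204703	-1
F7	-0.809017	0.587785	0	1
F5	-0.672125	0.707314	0.218986	1
F3	-0.480804	0.769563	0.420238	1
F1	-0.250547	0.769492	0.587459	1
FZ	0	0.707107	0.707107	0
F2	0.250547	0.769492	0.587459	-1
F4	0.480804	0.769563	0.420238	-1
F6	0.672125	0.707314	0.218986	-1
F8	0.809017	0.587785	0	-1
FT7	-0.951057	0.309017	0	1
FC5	-0.848835	0.412671	0.330427	1
FC3	-0.635947	0.462522	0.617774	1
FC1	-0.340147	0.452072	0.824579	1
FCZ	0	0.382683	0.92388	0
FC2	0.340147	0.452072	0.824579	-1
FC4	0.635947	0.462522	0.617774	-1
FC6	0.848835	0.412671	0.330427	-1
FT8	0.951057	0.309017	0	-1
T7	-1	0	0	1
C5	-0.92388	0	0.382683	1
C3	-0.707107	0	0.707107	1
C1	-0.382683	0	0.92388	1
CZ	0	0	1	0
C2	0.382683	0	0.92388	-1
C4	0.707107	0	0.707107	-1
C6	0.92388	0	0.382683	-1
T8	1	0	0	-1
TP7	-0.951057	-0.309017	0	1
CP5	-0.848835	-0.412671	0.330427	1
CP3	-0.635947	-0.462522	0.617774	1
CP1	-0.340147	-0.452072	0.824579	1
CPZ	0	-0.382683	0.92388	0
CP2	0.340147	-0.452072	0.824579	-1
CP4	0.635947	-0.462522	0.617774	-1
CP6	0.848835	-0.412671	0.330427	-1
TP8	0.951057	-0.309017	0	-1
P7	-0.809017	-0.587785	0	1
P5	-0.672125	-0.707314	0.218986	1
P3	-0.480804	-0.769563	0.420238	1
P1	-0.250547	-0.769492	0.587459	1
PZ	0	-0.707107	0.707107	0
P2	0.250547	-0.769492	0.587459	-1
P4	0.480804	-0.769563	0.420238	-1
P6	0.672125	-0.707314	0.218986	-1
P8	0.809017	-0.587785	0	-1
PO7	-0.587785	-0.809017	0	1
PO5	-0.458646	-0.882505	0.104064	1
PO3	-0.314415	-0.926952	0.204703	1
POZ	0	-0.92388	0.382683	0
PO4	0.314415	-0.926952	0.204703	-1
PO6	0.458646	-0.882505	0.104064	-1
PO8	0.587785	-0.809017	0	-1
CB1	-0.285494	-0.878662	-0.382683	1
O1	-0.309017	-0.951057	0	1
OZ	0	-1	0	0
O2	0.309017	-0.951057	0	-1
CB2	0.285494	-0.878662	-0.382683	-1
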