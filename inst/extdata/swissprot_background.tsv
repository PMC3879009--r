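# source: UniProtKB/Swiss-Prot global residue frequencies (frozen snapshot, circa 2013 releases)
A	0.082657860502351646
C	0.013709596717702393
D	0.054638246772740921
E	0.067547283098168723
F	0.038627038927249079
G	0.070849594716301423
H	0.022715901130791555
I	0.059741819273491446
K	0.058440908636045237
L	0.096667667367157012
M	0.024216951866306416
N	0.040628439907935555
P	0.047032923046132297
Q	0.039327529270489346
R	0.055338737115981196
S	0.065645952166516558
T	0.053437406184329031
V	0.068748123686580606
W	0.010807565295706997
Y	0.029220454318022619
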