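label,side,x,y
Fp1,left,-0.085,0.95
Fp2,right,0.085,0.95
AF7,left,-0.63,0.75
AF3,left,-0.315,0.75
AF4,right,0.315,0.75
AF8,right,0.63,0.75
F9,left,-0.894,0.55
F7,left,-0.767,0.55
F5,left,-0.579,0.55
F3,left,-0.383,0.55
F1,left,-0.17,0.55
Fz,midline,0,0.55
F2,right,0.17,0.55
F4,right,0.383,0.55
F6,right,0.579,0.55
F8,right,0.767,0.55
F10,right,0.894,0.55
FT9,left,-1.006,0.3
FT7,left,-0.862,0.3
FC5,left,-0.655,0.28
FC3,left,-0.434,0.28
FC1,left,-0.193,0.28
FC2,right,0.193,0.28
FC4,right,0.434,0.28
FC6,right,0.655,0.28
FT8,right,0.862,0.3
FT10,right,1.006,0.3
T7,left,-0.9,0
C5,left,-0.68,0
C3,left,-0.45,0
C1,left,-0.2,0
Cz,midline,0,0
C2,right,0.2,0
C4,right,0.45,0
C6,right,0.68,0
T8,right,0.9,0
TP9,left,-1.006,-0.3
TP7,left,-0.862,-0.3
CP5,left,-0.655,-0.28
CP3,left,-0.434,-0.28
CP1,left,-0.193,-0.28
CPz,midline,0,-0.28
CP2,right,0.193,-0.28
CP4,right,0.434,-0.28
CP6,right,0.655,-0.28
TP8,right,0.862,-0.3
TP10,right,1.006,-0.3
P7,left,-0.767,-0.55
P5,left,-0.579,-0.55
P3,left,-0.383,-0.55
P1,left,-0.17,-0.55
Pz,midline,0,-0.55
P2,right,0.17,-0.55
P4,right,0.383,-0.55
P6,right,0.579,-0.55
P8,right,0.767,-0.55
PO7,left,-0.63,-0.75
PO3,left,-0.315,-0.75
POz,midline,0,-0.75
PO4,right,0.315,-0.75
PO8,right,0.63,-0.75
O1,left,-0.085,-0.95
Oz,midline,0,-0.95
O2,right,0.085,-0.95
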