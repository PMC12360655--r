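channel,x,y,z,x2d,y2d
Fp1,-0.308832,0.950476,-0.034895,-0.496194,1.527108
AF7,-0.587429,0.808523,-0.034895,-0.943809,1.299035
AF3,-0.406242,0.871200,0.275642,-0.545822,1.170534
F1,-0.286968,0.710262,0.642789,-0.326909,0.809118
F3,-0.545008,0.673029,0.499998,-0.659024,0.813827
F5,-0.728991,0.633706,0.258822,-0.987908,0.858781
F7,-0.808523,0.587429,-0.034895,-1.299035,0.943809
FT7,-0.950476,0.308832,-0.034895,-1.527108,0.496194
FC5,-0.887885,0.340832,0.309021,-1.173165,0.450342
FC3,-0.676378,0.359631,0.642789,-0.770518,0.409686
FC1,-0.374705,0.374705,0.848052,-0.394918,0.394918
C1,-0.390727,-0.000000,0.920507,-0.401421,-0.000000
C3,-0.719336,-0.000000,0.694662,-0.802846,-0.000000
C5,-0.933580,-0.000000,0.358369,-1.204276,-0.000000
T7,-0.999391,-0.000000,-0.034895,-1.605698,-0.000000
TP7,-0.950476,-0.308832,-0.034895,-1.527108,-0.496194
CP5,-0.887885,-0.340832,0.309021,-1.173165,-0.450342
CP3,-0.676378,-0.359631,0.642789,-0.770518,-0.409686
CP1,-0.374705,-0.374705,0.848052,-0.394918,-0.394918
P1,-0.286968,-0.710262,0.642789,-0.326909,-0.809118
P3,-0.545008,-0.673029,0.499998,-0.659024,-0.813827
P5,-0.728991,-0.633706,0.258822,-0.987908,-0.858781
P7,-0.808523,-0.587429,-0.034895,-1.299035,-0.943809
P9,-0.733218,-0.532714,-0.422619,-1.623803,-1.179761
PO7,-0.587429,-0.808523,-0.034895,-0.943809,-1.299035
PO3,-0.406242,-0.871200,0.275642,-0.545822,-1.170534
O1,-0.308832,-0.950476,-0.034895,-0.496194,-1.527108
Iz,0.000000,-0.906306,-0.422622,0.000000,-2.007132
Oz,0.000000,-0.999391,-0.034895,0.000000,-1.605698
POz,0.000000,-0.933580,0.358369,0.000000,-1.204276
Pz,0.000000,-0.719336,0.694662,0.000000,-0.802846
CPz,0.000000,-0.390727,0.920507,0.000000,-0.401421
Fpz,0.000000,0.999391,-0.034895,0.000000,1.605698
Fp2,0.308832,0.950476,-0.034895,0.496194,1.527108
AF8,0.587429,0.808523,-0.034895,0.943809,1.299035
AF4,0.406242,0.871200,0.275642,0.545822,1.170534
AFz,0.000000,0.933580,0.358369,0.000000,1.204276
Fz,0.000000,0.719336,0.694662,0.000000,0.802846
F2,0.286968,0.710262,0.642789,0.326909,0.809118
F4,0.545008,0.673029,0.499998,0.659024,0.813827
F6,0.728991,0.633706,0.258822,0.987908,0.858781
F8,0.808523,0.587429,-0.034895,1.299035,0.943809
FT8,0.950476,0.308832,-0.034895,1.527108,0.496194
FC6,0.887885,0.340832,0.309021,1.173165,0.450342
FC4,0.676378,0.359631,0.642789,0.770518,0.409686
FC2,0.374705,0.374705,0.848052,0.394918,0.394918
FCz,0.000000,0.390727,0.920507,0.000000,0.401421
Cz,0.000000,0.000000,1.000000,0.000000,0.000000
C2,0.390727,0.000000,0.920507,0.401421,0.000000
C4,0.719336,0.000000,0.694662,0.802846,0.000000
C6,0.933580,0.000000,0.358369,1.204276,0.000000
T8,0.999391,0.000000,-0.034895,1.605698,0.000000
TP8,0.950476,-0.308832,-0.034895,1.527108,-0.496194
CP6,0.887885,-0.340832,0.309021,1.173165,-0.450342
CP4,0.676378,-0.359631,0.642789,0.770518,-0.409686
CP2,0.374705,-0.374705,0.848052,0.394918,-0.394918
P2,0.286968,-0.710262,0.642789,0.326909,-0.809118
P4,0.545008,-0.673029,0.499998,0.659024,-0.813827
P6,0.728991,-0.633706,0.258822,0.987908,-0.858781
P8,0.808523,-0.587429,-0.034895,1.299035,-0.943809
P10,0.733218,-0.532714,-0.422619,1.623803,-1.179761
PO8,0.587429,-0.808523,-0.034895,0.943809,-1.299035
PO4,0.406242,-0.871200,0.275642,0.545822,-1.170534
O2,0.308832,-0.950476,-0.034895,0.496194,-1.527108
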