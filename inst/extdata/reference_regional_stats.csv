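region,parameter,group,mean,sd,n
LVOT,diameter,control,28,5,23
LVOT,diameter,bav,29,4,73
AAo,diameter,control,28,4,23
AAo,diameter,bav,40,7,73
Arch,diameter,control,25,3,23
Arch,diameter,bav,26,5,73
PDAo,diameter,control,20,3,23
PDAo,diameter,bav,23,4,73
DDAo,diameter,control,18,3,23
DDAo,diameter,bav,20,3,73
LVOT,indexedDiameter,control,15,2,23
LVOT,indexedDiameter,bav,14,2,73
AAo,indexedDiameter,control,15,3,23
AAo,indexedDiameter,bav,20,4,73
Arch,indexedDiameter,control,13,2,23
Arch,indexedDiameter,bav,13,3,73
PDAo,indexedDiameter,control,11,2,23
PDAo,indexedDiameter,bav,11,2,73
DDAo,indexedDiameter,control,10,2,23
DDAo,indexedDiameter,bav,10,2,73
LVOT,peakVelocity,control,1.3,0.2,23
LVOT,peakVelocity,bav,1.9,1.0,73
AAo,peakVelocity,control,1.5,0.3,23
AAo,peakVelocity,bav,2.6,1.2,73
Arch,peakVelocity,control,1.2,0.2,23
Arch,peakVelocity,bav,1.5,0.8,73
PDAo,peakVelocity,control,1.2,0.3,23
PDAo,peakVelocity,bav,1.3,0.8,73
DDAo,peakVelocity,control,1.4,0.4,23
DDAo,peakVelocity,bav,1.2,0.5,73
LVOT,ke,control,1.9,0.5,23
LVOT,ke,bav,2.6,1.8,73
AAo,ke,control,1.8,0.6,23
AAo,ke,bav,2.3,1.2,73
Arch,ke,control,1.5,0.6,23
Arch,ke,bav,1.7,1.0,73
PDAo,ke,control,1.8,0.7,23
PDAo,ke,bav,1.7,1.1,73
DDAo,ke,control,2.0,0.9,23
DDAo,ke,bav,1.6,0.9,73
LVOT,ff,control,0.18,0.04,23
LVOT,ff,bav,0.15,0.06,73
AAo,ff,control,0.18,0.04,23
AAo,ff,bav,0.12,0.03,73
Arch,ff,control,0.17,0.04,23
Arch,ff,bav,0.14,0.04,73
PDAo,ff,control,0.19,0.05,23
PDAo,ff,bav,0.16,0.05,73
DDAo,ff,control,0.22,0.07,23
DDAo,ff,bav,0.17,0.05,73
LVOT,rf,control,0.025,0.01,23
LVOT,rf,bav,0.045,0.05,73
AAo,rf,control,0.011,0.001,23
AAo,rf,bav,0.039,0.02,73
Arch,rf,control,0.010,0.006,23
Arch,rf,bav,0.029,0.02,73
PDAo,rf,control,0.010,0.01,23
PDAo,rf,bav,0.019,0.02,73
DDAo,rf,control,0.005,0.004,23
DDAo,rf,bav,0.015,0.025,73
LVOT,stasis,control,33,9,23
LVOT,stasis,bav,22,12,73
AAo,stasis,control,50,10,23
AAo,stasis,bav,23,11,73
Arch,stasis,control,52,10,23
Arch,stasis,bav,32,16,73
PDAo,stasis,control,53,10,23
PDAo,stasis,bav,35,18,73
DDAo,stasis,control,43,13,23
DDAo,stasis,bav,38,17,73
global,age,control,37,14,23
global,age,bav,49,16,73
global,bsa,control,1.9,0.3,23
global,bsa,bav,2.0,0.3,73
AAo,rf,bav_nondilated,0.033,0.015,22
AAo,rf,bav_moderate,0.037,0.016,24
AAo,rf,bav_severe,0.045,0.016,27
Arch,rf,bav_nondilated,0.018,0.010,22
Arch,rf,bav_moderate,0.027,0.017,24
Arch,rf,bav_severe,0.039,0.018,27
AAo,stasis,bav_nondilated,31,13,22
AAo,stasis,bav_moderate,20,9,24
AAo,stasis,bav_severe,19,10,27
Arch,stasis,bav_nondilated,41,15,22
Arch,stasis,bav_moderate,33,17,24
Arch,stasis,bav_severe,27,14,27
DDAo,stasis,bav_type0,30,18,19
DDAo,stasis,bav_type1,41,16,47
Arch,peakVelocity,bav_type1rn,2.1,1.4,11
Arch,peakVelocity,bav_type1rl,1.4,0.5,36
Arch,peakVelocity,bav_type0,1.4,0.4,19
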