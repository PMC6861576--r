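# Vibrational assignments for DFB: scaled B3LYP/cc-pVDZ wavenumbers (cm-1), IR intensity (KM/mole), Raman activity (A^4/amu), observed IR and Raman bands (cm-1)
calc,ir_int,raman_act,obs_ir,obs_raman,assignment
3116,2.65,7.17,,3110,uCH
3095,0.18,278.20,3100,3095,uCH
3082,0.05,14.85,3083,,uCH
1668,54.80,238.06,1670,1672,uC=O
1666,267.94,28.23,1655,1658,uC=O
1568,58.71,2.51,1555,,uRing
1387,28.78,0.18,1382,,uRing
1315,3.94,5.86,1320,1320,uRing
1312,10.57,0.91,1305,1306,uRing
1253,0.01,8.39,,1250,dCH
1227,274.81,3.76,1235,,uCF
1225,15.00,27.33,1215,1218,uCF
1177,285.78,15.20,1160,1165,dCH
1119,223.62,2.30,1110,,dCH
1069,0.31,4.63,,1060,dCH
1019,0.29,8.52,1020,,uCC
970,0.01,0.42,,972,gCH
945,4.12,0.56,957,,gCH
841,99.96,1.68,845,850,gCH
840,64.44,2.64,,840,gCH
810,1.63,56.71,,808,uRing
806,4.83,7.99,805,,uRing
758,36.09,0.71,757,760,tRing
691,5.56,0.38,,700,tRing
619,4.80,2.26,,622,dRing
603,1.02,0.86,600,600,dRing
501,1.49,0.09,500,500,tRing
433,1.40,3.81,,435,tRing
415,19.67,0.28,,420,dRing
407,0.09,0.30,,405,tRing
356,1.07,2.29,,355,tC=O
267,0.33,0.86,,270,tC=O
261,26.65,0.65,,258,tRing
226,0.04,1.25,,225,tRing
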