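# Vibrational assignments for DMB: scaled B3LYP/cc-pVDZ wavenumbers (cm-1), IR intensity (KM/mole), Raman activity (A^4/amu), observed IR and Raman bands (cm-1)
calc,ir_int,raman_act,obs_ir,obs_raman,assignment
3107,0.85,13.43,3100,,uCH
3085,0.01,149.69,3070,3070,uCH
3053,27.49,39.15,3050,3050,uCH
3046,31.23,1.27,3045,3030,uCH
3000,11.51,81.37,,3000,uCH3
2998,15.50,71.18,,2995,uCH3
2968,20.05,77.64,2965,2960,uCH3
2967,4.41,195.52,2965,2960,uCH3
2912,4.86,684.39,2910,2913,uCH3
2911,44.50,38.39,2910,2913,uCH3
1667,69.31,2.45,1720,,uC=O
1665,290.83,24.15,1660,1660,uC=O
1593,227.58,93.33,1598,,uRing
1592,32.38,713.12,,1580,uRing
1549,2.40,3.84,1555,,uRing
1411,40.78,2.71,,1410,dCH3
1398,7.00,18.39,1400,,dCH3
1379,10.23,0.08,1377,1377,dCH3
1340,0.01,83.01,1345,1340,dCH3
1339,0.23,11.38,1345,1340,dCH3
1304,4.91,0.02,1302,1300,uRing
1188,0.42,52.18,,1190,dCH
1186,250.05,18.64,1184,1180,dCH
1143,245.11,10.23,1145,,dCH
1089,18.74,1.26,1085,,dCH
1024,0.13,9.29,1025,,uCC
1009,4.09,0.70,,1010,dCH3
992,10.35,0.06,998,,dCH3
957,0.65,7.13,955,,dCH3
862,55.22,0.87,870,870,gCH
833,5.11,3.05,835,836,gCH
824,48.77,0.83,825,,gCH
812,18.90,2.71,808,810,uRing
787,0.09,61.46,,788,uRing
768,6.66,2.82,770,,gCH
738,97.08,1.30,740,,gCH
624,0.79,2.16,,625,dRing
605,3.68,1.14,607,603,dRing
587,54.99,0.33,588,,dRing
495,15.53,3.35,494,,tRing
414,0.28,6.25,,412,tRing
401,6.72,1.73,,400,dRing
355,0.30,0.33,,357,tRing
341,0.15,2.26,,340,tCH3
249,12.12,1.04,,250,tRing
248,19.01,1.50,,244,tC=O
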