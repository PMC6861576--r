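# Vibrational assignments for DCB: scaled B3LYP/cc-pVDZ wavenumbers (cm-1), IR intensity (KM/mole), Raman activity (A^4/amu), observed IR bands (cm-1; no Raman bands reported)
calc,ir_int,raman_act,obs_ir,obs_raman,assignment
3095,0.02,2.37,3100,,uCH
3082,0.01,71.32,3080,,uCH
3082,0.18,6.34,3080,,uCH
1670,61.75,4.31,1665,,uC=O
1667,304.59,2.95,1665,,uC=O
1573,36.71,7.37,1575,,uRing
1547,52.98,3.63,1535,,uRing
1302,5.74,2.02,1308,,uRing
1298,14.46,0.43,1297,,uRing
1179,316.87,21.10,1177,,dCH
1021,0.50,14.10,1015,,uCC
971,0.17,0.52,965,,gCH
948,0.07,1.06,946,,gCH
862,54.58,0.12,858,,gCH
832,34.15,3.88,835,,uRing
769,46.83,0.28,766,,uRing
733,0.45,35.82,735,,gCH
719,16.68,1.11,710,,uCCl
688,0.82,0.89,690,,uCCl
476,3.13,0.92,470,,tRing
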