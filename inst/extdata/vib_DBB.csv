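# Vibrational assignments for DBB: scaled B3LYP/cc-pVDZ wavenumbers (cm-1), IR intensity (KM/mole), Raman activity (A^4/amu), observed IR bands (cm-1; no Raman bands reported)
calc,ir_int,raman_act,obs_ir,obs_raman,assignment
3114,1.74,4.77,3100,,uCH
3088,1.16,2.27,3090,,uCH
3082,0.47,8.58,3050,,uCH
1669,64.43,5.82,1670,,uC=O
1666,318.06,3.70,1650,,uC=O
1568,336.69,9.76,1570,,uRing
1273,14.10,2.13,1275,,uRing
1179,295.30,2.61,1177,,dCH
1081,12.85,1.04,1080,,dCH
1020,0.75,20.91,1015,,uCC
970,0.20,0.53,965,,gCH
947,0.04,1.34,945,,gCH
829,26.95,4.49,833,,uRing
764,50.50,0.24,763,,uRing
724,7.13,2.01,725,,gCH
664,14.08,6.31,670,,uCBr
611,4.21,1.11,610,,uCBr
496,28.90,1.28,498,,dRing
467,4.82,0.70,465,,tRing
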