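row,sample,mean,sd
UFAA,M-C-JH,73.24,4.18
UFAA,M-T-JH,57.29,5.60
UFAA,M-T-CJ,75.21,8.45
UFAA,H-C-JH,98.77,12.62
UFAA,H-T-JH,69.22,7.48
UFAA,H-T-CJ,66.51,3.18
UFAA,G-C-JH,61.26,4.75
UFAA,G-T-JH,78.17,1.81
UFAA,G-T-CJ,56.47,4.65
SFAA,M-C-JH,2175.62,114.83
SFAA,M-T-JH,2266.51,101.05
SFAA,M-T-CJ,2070.49,265.02
SFAA,H-C-JH,797.18,33.58
SFAA,H-T-JH,640.88,61.28
SFAA,H-T-CJ,824.66,31.55
SFAA,G-C-JH,359.52,32.15
SFAA,G-T-JH,398.07,5.66
SFAA,G-T-CJ,432.81,42.93
BFAA,M-C-JH,158.36,8.57
BFAA,M-T-JH,219.27,4.61
BFAA,M-T-CJ,256.85,48.42
BFAA,H-C-JH,569.52,39.45
BFAA,H-T-JH,403.75,49.31
BFAA,H-T-CJ,422.25,20.25
BFAA,G-C-JH,126.08,7.17
BFAA,G-T-JH,129.27,1.81
BFAA,G-T-CJ,129.28,9.89
FAA,M-C-JH,2435.35,129.99
FAA,M-T-JH,2592.70,105.33
FAA,M-T-CJ,2464.05,330.77
FAA,H-C-JH,1511.28,80.64
FAA,H-T-JH,1145.47,121.41
FAA,H-T-CJ,1347.76,56.14
FAA,G-C-JH,559.47,42.87
FAA,G-T-JH,621.44,9.04
FAA,G-T-CJ,631.92,56.54
EUC,M-C-JH,9.01,1.39
EUC,M-T-JH,6.18,1.00
EUC,M-T-CJ,7.51,3.06
EUC,H-C-JH,0.32,0.03
EUC,H-T-JH,0.01,0.00
EUC,H-T-CJ,0.01,0.00
EUC,G-C-JH,128.41,6.49
EUC,G-T-JH,165.39,18.60
EUC,G-T-CJ,108.84,11.31
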