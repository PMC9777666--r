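sample,compound,mean,sd
M-C-JH,Asp,7.12,0.84
M-T-JH,Asp,6.88,0.86
M-T-CJ,Asp,6.79,0.72
H-C-JH,Asp,13.55,4.31
H-T-JH,Asp,4.10,0.55
H-T-CJ,Asp,3.76,0.13
G-C-JH,Asp,2.87,0.71
G-T-JH,Asp,5.80,0.14
G-T-CJ,Asp,2.28,0.07
M-C-JH,Glu,66.12,3.45
M-T-JH,Glu,50.41,4.92
M-T-CJ,Glu,68.42,7.80
H-C-JH,Glu,85.22,8.31
H-T-JH,Glu,65.12,6.94
H-T-CJ,Glu,62.75,3.06
G-C-JH,Glu,58.39,4.79
G-T-JH,Glu,72.36,1.67
G-T-CJ,Glu,54.19,4.60
M-C-JH,Thr,60.64,3.44
M-T-JH,Thr,72.68,16.6
M-T-CJ,Thr,79.17,10.22
H-C-JH,Thr,87.71,11.25
H-T-JH,Thr,71.83,7.03
H-T-CJ,Thr,83.14,4.86
G-C-JH,Thr,13.81,1.16
G-T-JH,Thr,22.70,0.40
G-T-CJ,Thr,14.43,1.10
M-C-JH,Ser,39.07,2.45
M-T-JH,Ser,59.76,4.84
M-T-CJ,Ser,44.86,6.57
H-C-JH,Ser,55.30,7.02
H-T-JH,Ser,40.35,4.29
H-T-CJ,Ser,43.34,1.31
G-C-JH,Ser,9.71,0.83
G-T-JH,Ser,13.03,0.17
G-T-CJ,Ser,11.16,1.13
M-C-JH,Gly,553.78,29.75
M-T-JH,Gly,539.35,32.65
M-T-CJ,Gly,496.87,70.29
H-C-JH,Gly,108.36,7.46
H-T-JH,Gly,108.12,10.20
H-T-CJ,Gly,110.90,6.13
G-C-JH,Gly,28.74,2.24
G-T-JH,Gly,37.91,0.53
G-T-CJ,Gly,35.36,2.26
M-C-JH,Ala,586.54,35.72
M-T-JH,Ala,599.40,24.66
M-T-CJ,Ala,522.50,61.16
H-C-JH,Ala,165.35,2.96
H-T-JH,Ala,143.71,11.59
H-T-CJ,Ala,174.98,4.30
G-C-JH,Ala,53.12,4.03
G-T-JH,Ala,58.52,1.02
G-T-CJ,Ala,77.30,6.30
M-C-JH,Arg,671.10,30.47
M-T-JH,Arg,673.59,35.43
M-T-CJ,Arg,644.64,86.96
H-C-JH,Arg,311.77,10.47
H-T-JH,Arg,207.29,23.34
H-T-CJ,Arg,314.75,14.65
G-C-JH,Arg,188.07,19.48
G-T-JH,Arg,200.29,3.47
G-T-CJ,Arg,215.50,21.05
M-C-JH,Pro,264.48,15.21
M-T-JH,Pro,321.72,11.66
M-T-CJ,Pro,282.44,31.12
H-C-JH,Pro,68.69,4.70
H-T-JH,Pro,69.58,5.00
H-T-CJ,Pro,97.55,3.46
G-C-JH,Pro,66.07,6.12
G-T-JH,Pro,65.61,1.80
G-T-CJ,Pro,79.06,25.39
M-C-JH,Val,21.58,1.47
M-T-JH,Val,28.30,1.55
M-T-CJ,Val,29.82,5.33
H-C-JH,Val,69.32,7.35
H-T-JH,Val,54.48,6.02
H-T-CJ,Val,53.33,2.35
G-C-JH,Val,10.26,1.09
G-T-JH,Val,10.49,0.08
G-T-CJ,Val,11.12,0.63
M-C-JH,Met,24.05,1.95
M-T-JH,Met,45.66,2.52
M-T-CJ,Met,56.35,11.02
H-C-JH,Met,40.87,1.00
H-T-JH,Met,31.16,3.21
H-T-CJ,Met,32.58,1.64
G-C-JH,Met,11.43,1.50
G-T-JH,Met,14.69,0.10
G-T-CJ,Met,11.78,1.85
M-C-JH,Leu,21.32,1.12
M-T-JH,Leu,26.37,1.06
M-T-CJ,Leu,24.94,3.49
H-C-JH,Leu,107.98,8.91
H-T-JH,Leu,75.16,9.69
H-T-CJ,Leu,78.28,3.79
G-C-JH,Leu,8.61,1.26
G-T-JH,Leu,9.65,0.48
G-T-CJ,Leu,10.39,0.61
M-C-JH,Tyr,15.98,0.98
M-T-JH,Tyr,22.71,0.97
M-T-CJ,Tyr,26.15,6.09
H-C-JH,Tyr,81.88,5.63
H-T-JH,Tyr,58.44,6.78
H-T-CJ,Tyr,58.38,3.00
G-C-JH,Tyr,14.41,0.76
G-T-JH,Tyr,14.25,0.52
G-T-CJ,Tyr,14.06,1.02
M-C-JH,Phe,11.20,0.81
M-T-JH,Phe,19.38,1.07
M-T-CJ,Phe,21.89,5.53
H-C-JH,Phe,96.28,6.77
H-T-JH,Phe,64.40,8.09
H-T-CJ,Phe,69.40,3.17
G-C-JH,Phe,16.46,1.50
G-T-JH,Phe,19.12,0.22
G-T-CJ,Phe,19.05,1.55
M-C-JH,Lys,55.50,3.00
M-T-JH,Lys,63.40,0.92
M-T-CJ,Lys,89.42,14.97
H-C-JH,Lys,130.93,7.99
H-T-JH,Lys,95.50,12.04
H-T-CJ,Lys,105.29,4.39
G-C-JH,Lys,49.89,2.83
G-T-JH,Lys,52.76,2.13
G-T-CJ,Lys,49.01,4.36
M-C-JH,His,22.14,0.92
M-T-JH,His,45.93,1.19
M-T-CJ,His,51.14,10.37
H-C-JH,His,35.37,4.66
H-T-JH,His,26.07,2.70
H-T-CJ,His,27.76,2.36
G-C-JH,His,20.89,2.36
G-T-JH,His,17.20,0.07
G-T-CJ,His,20.10,1.38
M-C-JH,Ile,10.65,0.67
M-T-JH,Ile,13.18,0.65
M-T-CJ,Ile,13.50,2.86
H-C-JH,Ile,47.77,1.83
H-T-JH,Ile,29.69,4.11
H-T-CJ,Ile,29.81,1.49
G-C-JH,Ile,5.57,0.58
G-T-JH,Ile,5.79,0.52
G-T-CJ,Ile,5.55,0.50
M-C-JH,Cys,4.08,1.01
M-T-JH,Cys,3.97,0.46
M-T-CJ,Cys,5.14,1.23
H-C-JH,Cys,4.94,2.41
H-T-JH,Cys,0.46,0.29
H-T-CJ,Cys,1.76,0.14
G-C-JH,Cys,1.17,0.11
G-T-JH,Cys,1.25,0.11
G-T-CJ,Cys,1.58,0.24
M-C-JH,GMP,2.97,0.92
M-T-JH,GMP,3.00,0.45
M-T-CJ,GMP,2.49,1.22
H-C-JH,GMP,ND,ND
H-T-JH,GMP,ND,ND
H-T-CJ,GMP,ND,ND
G-C-JH,GMP,73.79,1.72
G-T-JH,GMP,72.17,7.18
G-T-CJ,GMP,58.56,1.26
M-C-JH,IMP,81.39,8.02
M-T-JH,IMP,72.79,9.96
M-T-CJ,IMP,63.56,18.65
H-C-JH,IMP,2.75,0.02
H-T-JH,IMP,ND,ND
H-T-CJ,IMP,ND,ND
G-C-JH,IMP,1564.26,66.36
G-T-JH,IMP,1633.55,180.88
G-T-CJ,IMP,1454.08,33.69
M-C-JH,AMP,123.63,16.01
M-T-JH,AMP,109.62,22.11
M-T-CJ,AMP,99.71,33.01
H-C-JH,AMP,0.45,0.28
H-T-JH,AMP,ND,ND
H-T-CJ,AMP,ND,ND
G-C-JH,AMP,377.55,41.03
G-T-JH,AMP,361.10,30.00
G-T-CJ,AMP,295.09,23.89
M-C-JH,Hx,1.94,0.83
M-T-JH,Hx,1.94,0.12
M-T-CJ,Hx,1.41,0.75
H-C-JH,Hx,5.42,0.08
H-T-JH,Hx,6.37,0.45
H-T-CJ,Hx,5.86,1.68
G-C-JH,Hx,8.61,1.61
G-T-JH,Hx,8.84,1.27
G-T-CJ,Hx,8.29,0.84
M-C-JH,HxR,11.83,1.50
M-T-JH,HxR,12.68,0.78
M-T-CJ,HxR,10.55,3.39
H-C-JH,HxR,15.83,1.23
H-T-JH,HxR,20.01,1.21
H-T-CJ,HxR,18.47,5.89
G-C-JH,HxR,83.52,5.90
G-T-JH,HxR,74.63,7.77
G-T-CJ,HxR,70.80,3.19
M-C-JH,Na,146.76,13.26
M-T-JH,Na,127.57,4.84
M-T-CJ,Na,142.61,14.80
H-C-JH,Na,146.15,16.68
H-T-JH,Na,131.52,8.08
H-T-CJ,Na,124.51,8.31
G-C-JH,Na,59.82,19.38
G-T-JH,Na,61.21,2.62
G-T-CJ,Na,59.67,5.75
M-C-JH,K,431.64,68.37
M-T-JH,K,378.33,14.62
M-T-CJ,K,360.51,39.80
H-C-JH,K,174.83,15.04
H-T-JH,K,157.65,7.83
H-T-CJ,K,128.33,5.89
G-C-JH,K,129.03,53.99
G-T-JH,K,165.08,6.64
G-T-CJ,K,183.69,7.28
M-C-JH,Mg,36.45,1.85
M-T-JH,Mg,36.12,1.13
M-T-CJ,Mg,40.46,4.13
H-C-JH,Mg,20.84,1.66
H-T-JH,Mg,17.17,0.74
H-T-CJ,Mg,14.52,0.72
G-C-JH,Mg,57.24,23.57
G-T-JH,Mg,58.66,1.57
G-T-CJ,Mg,65.97,0.24
M-C-JH,Ca,129.41,13.59
M-T-JH,Ca,105.95,13.38
M-T-CJ,Ca,152.74,22.69
H-C-JH,Ca,89.22,52.46
H-T-JH,Ca,69.97,15.29
H-T-CJ,Ca,53.51,9.84
G-C-JH,Ca,52.98,21.51
G-T-JH,Ca,72.31,29.63
G-T-CJ,Ca,59.64,15.30
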