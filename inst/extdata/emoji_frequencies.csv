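emoji,label,valence,M-C-JH,M-T-JH,M-T-CJ,H-C-JH,H-T-JH,H-T-CJ,G-C-JH,G-T-JH,G-T-CJ,p_printed
kissing-closed-eyes,Kissing face with closed eyes,positive,9,15,12,4,15,15,9,12,10,0.192
stuck-out-tongue,Face with stuck-out tongue,positive,10,7,16,9,11,16,10,12,17,0.166
stuck-out-tongue-winking,Face with stuck-out tongue and winking eyes,positive,0,0,0,0,0,0,0,0,0,1.000
stuck-out-tongue-closed-eyes,Face with stuck-out tongue and tightly closed eyes,positive,11,8,16,9,11,8,8,11,11,0.494
tears-of-joy,Face with tears of joy,positive,2,8,5,3,5,7,5,7,3,0.711
grinning,Grinning face,positive,26,20,33,13,25,25,23,30,24,0.050
smiling,Smiling face,positive,12,9,16,11,16,16,16,17,17,0.504
heart-eyes,Smiling face with heart-shaped eyes,positive,4,7,8,2,9,7,5,5,5,0.623
smiling-eyes,Smiling face with smiling eyes,positive,16,18,23,5,17,18,13,16,13,0.054
open-mouth-closed-eyes,Smiling face with open mouth and tightly closed eyes,positive,15,13,12,5,9,5,4,7,10,0.059
grinning-smiling-eyes,Grinning face with smiling eyes,positive,5,9,15,1,11,7,7,7,4,0.011
sunglasses,Smiling face with sunglasses,positive,3,7,1,0,3,3,2,0,0,0.019
smirking,Smirking face,positive,4,5,7,2,4,4,4,3,3,0.913
angry,Angry face,negative,8,3,4,15,4,8,7,3,3,0.003
medical-mask,Face with medical mask,negative,3,5,1,10,2,5,3,4,7,0.145
confused,Confused face,negative,12,12,8,23,14,12,19,19,18,0.040
crying,Crying face,negative,0,0,0,0,0,0,0,0,0,1.000
disappointed,Disappointed face,negative,5,3,2,8,2,8,3,1,0,0.030
screaming,Face screaming in fear,negative,4,7,1,17,5,10,5,2,3,0.0001
weary,Weary face,negative,2,3,1,11,1,7,8,1,2,0.001
cold-sweat,Face with cold sweat,negative,10,7,8,20,14,10,13,7,7,0.017
neutral,Neutral face,neutral,22,22,19,19,19,11,20,16,24,0.498
expressionless,Expressionless face,neutral,16,22,15,31,27,20,33,32,32,0.004
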