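dataset,NB,TAN,KCF,KDB,AODE
Adult,84.2,86.2,85.1,86.2,86.8
Breast-cancer-w,95.8,96.4,97.4,95.3,94.6
Census-income,76.3,93.6,89.9,94.9,94.9
Chess,88.7,90.7,90.0,90.0,92.4
Echocardiogram,66.4,67.2,67.9,65.6,66.4
German,74.7,72.7,75.2,71.1,73.0
Heart,80.2,80.7,80.8,81.9,80.4
Heart Disease,79.9,79.2,78.8,77.6,79.6
Mushrooms,98.0,100.0,100.0,100.0,100.0
Pima-ind-diabetes,75.5,76.2,76.2,75.5,76.3
Spambase,89.8,93.3,93.3,93.6,94.1
Tic-tac-toe,69.3,77.1,73.5,79.6,80.6
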