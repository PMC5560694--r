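metric,dataset,NB,TAN,AODE,KDB,KCF
sensitivity,Breast-cancer-w,0.969,0.973,0.965,0.958,0.971
sensitivity,Heart,0.840,0.853,0.860,0.853,0.806
sensitivity,Heart-disease-c,0.829,0.856,0.842,0.816,0.786
sensitivity,Pima-ind-diabetes,0.820,0.842,0.824,0.838,0.816
specificity,Breast-cancer-w,0.917,0.929,0.945,0.975,0.975
specificity,Heart,0.742,0.750,0.756,0.792,0.854
specificity,Heart-disease-c,0.748,0.741,0.813,0.776,0.846
specificity,Pima-ind-diabetes,0.634,0.612,0.631,0.619,0.642
bac,Breast-cancer-w,0.943,0.952,0.955,0.966,0.973
bac,Heart,0.798,0.802,0.808,0.826,0.830
bac,Heart-disease-c,0.788,0.798,0.802,0.797,0.816
bac,Pima-ind-diabetes,0.727,0.726,0.727,0.728,0.729
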