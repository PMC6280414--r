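dataset,method,g_mean,auc,f_measure
breast_cancer,w-elm,0.5679,0.8093,0.7658
breast_cancer,smote-elm,0.7816,0.7981,0.7584
breast_cancer,h-elm,0.5835,0.6584,0.5967
breast_cancer,pgm-elm,0.9212,0.9013,0.9354
liver_patient,w-elm,0.7827,0.7439,0.9127
liver_patient,smote-elm,0.6379,0.5198,0.9218
liver_patient,h-elm,0.5980,0.6919,0.7226
liver_patient,pgm-elm,0.8016,0.8581,0.9304
diabetic_retinopathy,w-elm,0.6555,0.7849,0.9207
diabetic_retinopathy,smote-elm,0.7554,0.7220,0.7404
diabetic_retinopathy,h-elm,0.6112,0.7493,0.6346
diabetic_retinopathy,pgm-elm,0.8778,0.8619,0.9715
pima_diabetes,w-elm,0.9360,0.9151,0.9724
pima_diabetes,smote-elm,0.6277,0.8792,0.5655
pima_diabetes,h-elm,0.5041,0.8580,0.5000
pima_diabetes,pgm-elm,0.9657,0.9324,0.9922
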