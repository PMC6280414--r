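dataset,attributes,minority,majority,train,test
breast_cancer,32,212,357,100,469
liver_patient,11,26,224,50,200
diabetic_retinopathy,20,100,300,100,300
pima_diabetes,9,117,517,200,434
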