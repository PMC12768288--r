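model,accuracy,precision,recall,f1
KOA-DT,0.8,0.7997,0.8176,0.8024
KOA-SVM,0.8786,0.8878,0.8818,0.8800
KOA-KNN,0.8429,0.8478,0.8510,0.8408
KOA-MLP,0.8857,0.8956,0.8894,0.8886
KOA-RF,0.8786,0.8860,0.8794,0.8766
KOA-GBDT,0.8929,0.9008,0.8927,0.8923
DT-stacking,0.8,0.7929,0.7921,0.7880
SVM-stacking,0.8714,0.8866,0.8772,0.8763
KNN-stacking,0.8786,0.8895,0.8844,0.8811
MLP-stacking,0.8714,0.8868,0.8732,0.8750
RF-stacking,0.9071,0.9145,0.9074,0.9077
GBDT-stacking,0.8714,0.8753,0.8707,0.8699
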