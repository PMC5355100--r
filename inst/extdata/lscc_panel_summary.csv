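cohort,marker,nPairs,meanNT,sdNT,meanLSCC,sdLSCC,p,auc,aucSE,sensitivity,specificity
training,ENST00000453324,24,1.19,1.63,3.74,3.94,0.001481,0.76,0.07,69,84
training,NR_028500,24,0.98,1.00,2.36,2.17,0.001293,0.70,0.07,73,65
training,UC011CLY.2,24,3.37,3.36,9.08,5.85,0.000013,0.77,0.06,84,66
training,NR_046326,24,2.16,2.44,6.91,5.40,0.000040,0.79,0.06,84,74
training,ENST00000441841,24,4.78,5.20,13.48,11.01,0.000288,0.76,0.06,73,73
validation,ENST00000453324,39,2.02,2.18,5.42,4.49,0.000010,0.77,0.05,64,80
validation,NR_028500,39,2.32,2.66,6.41,6.16,0.000191,0.73,0.06,75,68
validation,UC011CLY.2,39,3.94,4.02,12.64,10.02,0.000003,0.80,0.05,73,80
validation,NR_046326,39,4.12,4.53,10.65,8.36,0.000026,0.77,0.05,79,71
validation,ENST00000441841,39,8.10,10.80,20.10,16.92,0.000006,0.80,0.07,86,70
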