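sex,age_lo,age_hi,value
F,50,55,0.0027897649929395823
F,55,60,0.004485981716295674
F,60,65,0.007213522289465082
F,65,70,0.011599446255340002
F,70,75,0.018652074261560025
F,75,80,0.02999280022514766
F,80,85,0.04822884858439223
F,85,90,0.07755267325209479
F,90,95,0.12470579964234431
F,95,NA,0.2005286963337072
M,50,55,0.0055795299858791645
M,55,60,0.008971963432591348
M,60,65,0.014427044578930164
M,65,70,0.023198892510680004
M,70,75,0.03730414852312005
M,75,80,0.05998560045029532
M,80,85,0.09645769716878445
M,85,90,0.15510534650418958
M,90,95,0.24941159928468862
M,95,NA,0.4010573926674144
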