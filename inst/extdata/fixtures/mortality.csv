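sex,age_lo,age_hi,value
F,50,55,0.0025361499935814386
F,55,60,0.004078165196632431
F,60,65,0.006557747535877347
F,65,70,0.010544951141218183
F,70,75,0.016956431146872748
F,75,80,0.027266182022861508
F,80,85,0.04384440780399293
F,85,90,0.07050243022917708
F,90,95,0.11336890876576755
F,95,NA,0.18229881484882474
M,50,55,0.005072299987162877
M,55,60,0.008156330393264861
M,60,65,0.013115495071754694
M,65,70,0.021089902282436367
M,70,75,0.033912862293745495
M,75,80,0.054532364045723015
M,80,85,0.08768881560798586
M,85,90,0.14100486045835417
M,90,95,0.2267378175315351
M,95,NA,0.3645976296976495
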