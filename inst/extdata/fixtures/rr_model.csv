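crf_name,outcome,rr
prior_fracture,hip,2
prior_fracture,mof,1.8
parent_hip_fracture,hip,2.3
parent_hip_fracture,mof,1.5
smoking,hip,1.6
smoking,mof,1.2
glucocorticoids,hip,2.2
glucocorticoids,mof,1.6
rheumatoid_arthritis,hip,1.7
rheumatoid_arthritis,mof,1.4
alcohol,hip,1.7
alcohol,mof,1.4
gradient_of_risk,hip,2.4
gradient_of_risk,mof,1.6
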