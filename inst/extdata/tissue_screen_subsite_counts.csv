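location,n_positive,n_negative
splenic_flexure,2,0
sigmoid_colon,14,1
rectosigmoid_junction,9,2
descending_colon,3,0
rectum_NOS,5,0
colon_NOS,4,1
ascending_colon,3,2
hepatic_flexure,1,0
transverse_colon,1,0
other,1,0
unknown,1,0
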