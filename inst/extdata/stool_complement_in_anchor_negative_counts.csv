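sample_type,location,n_positive,n_negative
carcinoma,left_colon,5,3
carcinoma,right_colon,1,3
carcinoma,sigmoid_colon,8,5
carcinoma,rectum,7,6
adenoma,left_colon,5,12
adenoma,right_colon,1,16
adenoma,sigmoid_colon,8,15
adenoma,rectum,7,19
normal,unknown,6,202
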