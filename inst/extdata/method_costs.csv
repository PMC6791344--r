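method,description,itru_buy_in,oligo_buy_in,fixed_per_sample,variable_per_pool,pooled
1,standard primers + y-yoke ligation + indexed second PCR,500,103,18.86,NA,FALSE
2,standard primers + indexed fusion PCR + pooled second PCR,500,460,3.12,4.07,TRUE
3,indexed primers + pooled y-yoke ligation + pooled second PCR,500,290,1.39,17.52,TRUE
4,non-indexed fusion primers + indexed second PCR,500,40,4.44,NA,FALSE
5,indexed fusion primers + pooled second PCR,500,445,1.39,4.07,TRUE
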