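patient_id,n_focus,n_total,included
1,NA,NA,FALSE
2,1588,2974,TRUE
3,NA,NA,FALSE
4,1414,2397,TRUE
5,1774,2798,TRUE
6,1851,3382,TRUE
7,1697,3544,TRUE
8,2082,3926,TRUE
9,NA,NA,FALSE
10,789,3699,TRUE
11,438,492,TRUE
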