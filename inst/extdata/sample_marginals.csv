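variable,level,pct_entitled,count
sex,male,12.4,17629
sex,female,11.4,31368
age_band,75-79,5.5,19926
age_band,80-84,11.2,17135
age_band,85-89,20.4,9443
age_band,90-94,31.4,2300
age_band,95-100,43.5,193
homecare_self,no,2.4,26063
homecare_self,yes,22.4,22934
n_children_alive,0,13.2,3840
n_children_alive,1,12.2,6816
n_children_alive,2,10.5,18858
n_children_alive,3,11.4,11574
n_children_alive,4+,14.0,7909
ses_category,missing,11.6,4913
ses_category,<25%,11.8,30674
ses_category,25-50%,11.8,13242
ses_category,>=50%,8.3,168
total,total,11.7,48997
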