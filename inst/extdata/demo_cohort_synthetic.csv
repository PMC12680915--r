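id,sex,age_band,ses_category,n_children_alive,has_daughter,homecare_self,homecare_partner,g,death_month,entitlement_month,entitlement_type
1,female,75-79,<25%,2,TRUE,FALSE,TRUE,2,,,none
2,male,80-84,25-50%,1,FALSE,TRUE,TRUE,2,,3,PG
3,female,85-89,<25%,3,TRUE,TRUE,FALSE,2,,1,somatic
4,female,75-79,missing,0,FALSE,FALSE,TRUE,3,,,none
5,male,80-84,<25%,2,TRUE,FALSE,TRUE,3,,5,PG
6,female,90-94,<25%,4,TRUE,TRUE,TRUE,3,9,4,PG
7,male,75-79,25-50%,1,TRUE,FALSE,FALSE,4,,,none
8,female,80-84,<25%,2,FALSE,TRUE,TRUE,4,,,none
9,female,85-89,25-50%,3,TRUE,TRUE,TRUE,4,,6,somatic
10,male,75-79,<25%,2,TRUE,FALSE,TRUE,4,,,none
11,female,80-84,<25%,1,FALSE,FALSE,TRUE,5,,,none
12,male,85-89,missing,2,TRUE,TRUE,FALSE,5,,2,PG
13,female,75-79,<25%,3,TRUE,FALSE,TRUE,5,11,,none
14,female,80-84,25-50%,2,FALSE,TRUE,TRUE,5,,8,PG
15,male,75-79,<25%,0,FALSE,FALSE,TRUE,6,,,none
16,female,85-89,<25%,2,TRUE,TRUE,TRUE,6,,7,somatic
17,male,80-84,25-50%,1,TRUE,FALSE,FALSE,6,,,none
18,female,75-79,<25%,4,TRUE,FALSE,TRUE,6,,,none
19,male,90-94,<25%,2,TRUE,TRUE,TRUE,6,,12,PG
20,female,80-84,<25%,3,TRUE,FALSE,TRUE,6,,,none
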