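technique,scheme,rate_inr
rt_2drt_cobalt,CGHS,78689
rt_2drt_cobalt,ESIS,70000
rt_2drt_cobalt,RSBY_plus,24000
rt_2drt_cobalt,RAS,20000
rt_2drt_cobalt,RGJAY,20000
rt_2drt_cobalt,present_study,38714
rt_2drt_linac,CGHS,NA
rt_2drt_linac,ESIS,NA
rt_2drt_linac,RSBY_plus,60000
rt_2drt_linac,RAS,50000
rt_2drt_linac,RGJAY,50000
rt_2drt_linac,present_study,56064
rt_3dcrt,CGHS,NA
rt_3dcrt,ESIS,95000
rt_3dcrt,RSBY_plus,90000
rt_3dcrt,RAS,75000
rt_3dcrt,RGJAY,75000
rt_3dcrt,present_study,81594
rt_imrt_linac,CGHS,116010
rt_imrt_linac,ESIS,129000
rt_imrt_linac,RSBY_plus,120000
rt_imrt_linac,RAS,100000
rt_imrt_linac,RGJAY,100000
rt_imrt_linac,present_study,99107
rt_imrt_igrt,CGHS,169068
rt_imrt_igrt,ESIS,188000
rt_imrt_igrt,RSBY_plus,NA
rt_imrt_igrt,RAS,NA
rt_imrt_igrt,RGJAY,150000
rt_imrt_igrt,present_study,192914
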