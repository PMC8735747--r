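study_id,author,year,subgroup,design,quality_score,case_cc,case_ct,case_tt,control_cc,control_ct,control_tt,case_n,control_n
Vasconcelos2019,Vasconcelos,2019,Non-Asian,PB,7,155,47,3,144,53,8,205,205
Gao2016,Gao,2016,Asian,PB,8,91,46,20,101,48,11,157,160
Chen2012,Chen,2012,Asian,PB,7,558,171,27,629,173,13,756,815
Zhang2016,Zhang,2016,Asian,HB,8,332,117,28,364,101,12,477,477
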