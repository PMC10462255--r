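subject_id,best_pct_change,confirmed_recist,confirmed_irrecist,benefit_months,new_therapy_within_1yr,evaluable
S01,-60,TRUE,TRUE,24,FALSE,TRUE
S02,-55,TRUE,TRUE,26,FALSE,TRUE
S03,-35,FALSE,TRUE,10,FALSE,TRUE
S04,-15,FALSE,FALSE,9,FALSE,TRUE
S05,-10,FALSE,FALSE,8,FALSE,TRUE
S06,5,FALSE,FALSE,7,TRUE,TRUE
S07,25,FALSE,FALSE,3,TRUE,TRUE
S08,30,FALSE,FALSE,2,TRUE,TRUE
S09,10,FALSE,FALSE,3.5,TRUE,TRUE
S10,40,FALSE,FALSE,1.5,TRUE,TRUE
S11,22,FALSE,FALSE,2.5,TRUE,TRUE
S12,50,FALSE,FALSE,1,TRUE,TRUE
S13,15,FALSE,FALSE,4,TRUE,TRUE
S14,70,FALSE,FALSE,1,TRUE,TRUE
S15,25,FALSE,FALSE,0.5,TRUE,FALSE
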