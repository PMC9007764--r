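record_id,session_id,what,subcategory,where,how,who,start,end,is_interruption,interrupts_record_id
r1,S1,Documentation,drug-related,Physician desk,On computer,none,2018-10-16T09:00:00,2018-10-16T09:10:00,FALSE,
r2,S1,Gather information,non-drug-related,Patient room,Direct,Patient,2018-10-16T09:10:00,2018-10-16T09:25:00,FALSE,
r3,S1,Professional communication,non-drug-related,Physician desk,Direct,Nurse,2018-10-16T09:02:00,2018-10-16T09:03:00,TRUE,r1
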