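session_id,physician_id,affiliation,experience,session_start,session_end,n_new_patients,n_followup_patients
S1,P1,Medical,experienced,2018-10-16T09:00:00,2018-10-16T11:00:00,2,1
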