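patient_id,referral_date,pain_symptoms,stress_test,underlying_disease,mi_count,socioeconomic_performance,waiting_time,special_circumstances
P001,2021-02-01,8,5,10,0,3,7,1
P002,2021-01-15,9,9,8,7,6,2,0
P003,2021-03-10,3,2,4,1,5,9,2
P004,2021-01-03,10,9,9,8,7,4,3
P005,2021-02-20,6,6,5,5,4,5,1
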