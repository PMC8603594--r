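patient_id,age,drug,entry_date,route_class
PT001,74,Coumadin,2019-03-01,systemic
PT001,74,amiodarone,2019-03-01,systemic
PT001,74,aspirin,2019-03-01,systemic
PT001,74,lisinopril,2019-03-01,systemic
PT002,81,bupropion,2018-11-20,systemic
PT002,81,Prozac,2018-11-20,systemic
PT002,81,mirtazapine,2018-11-20,systemic
PT002,81,metformin,2018-11-20,systemic
PT002,81,latanoprost,2018-11-20,ophthalmic
PT003,69,tramadol,2019-05-14,systemic
PT003,69,trazodone,2019-05-14,systemic
PT004,66,atorvastatin,2019-02-02,systemic
PT004,66,metformin,2019-02-02,systemic
PT005,59,warfarin,2019-01-10,systemic
PT005,59,amiodarone,2019-01-10,systemic
PT006,77,enoxaparin,2019-04-03,systemic
PT006,77,warfarin,2019-04-03,systemic
PT007,72,ondansetron,2016-08-19,systemic
PT007,72,quetiapine,2019-08-19,systemic
PT008,85,hydrocortisone,2019-06-06,topical
PT008,85,omeprazole,2019-06-06,systemic
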