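patient_id,date,code,system
P001,2020-01-05,I251,ICD10
P001,2020-01-05,E11,ICD10
P001,2020-02-20,I200,ICD10
P001,2020-06-12,I500,ICD10
P001,2020-01-15,C07AB02,ATC
P001,2020-07-02,C07AB02,ATC
P002,2020-03-02,I214,ICD10
P002,2020-03-29,I251,ICD10
P002,2020-04-10,J441,ICD10
P002,2020-03-05,C09AA05,ATC
P003,2019-11-21,E112,ICD10
P003,2019-11-21,I10,ICD10
P003,2020-02-14,I251,ICD10
P003,2019-12-01,A10BA02,ATC
P004,2020-05-18,I500,ICD10
P004,2020-08-30,I255,ICD10
P004,2020-05-20,C03CA01,ATC
P004,2020-11-07,C07AB02,ATC
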