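code_prefix,condition,weight
I110,congestive_heart_failure,2
I130,congestive_heart_failure,2
I132,congestive_heart_failure,2
I255,congestive_heart_failure,2
I42,congestive_heart_failure,2
I43,congestive_heart_failure,2
I50,congestive_heart_failure,2
P290,congestive_heart_failure,2
F00,dementia,2
F01,dementia,2
F02,dementia,2
F03,dementia,2
F051,dementia,2
G30,dementia,2
G311,dementia,2
J40,chronic_pulmonary_disease,1
J41,chronic_pulmonary_disease,1
J42,chronic_pulmonary_disease,1
J43,chronic_pulmonary_disease,1
J44,chronic_pulmonary_disease,1
J45,chronic_pulmonary_disease,1
J46,chronic_pulmonary_disease,1
J47,chronic_pulmonary_disease,1
J60,chronic_pulmonary_disease,1
J684,chronic_pulmonary_disease,1
M05,rheumatic_disease,1
M06,rheumatic_disease,1
M315,rheumatic_disease,1
M32,rheumatic_disease,1
M33,rheumatic_disease,1
M34,rheumatic_disease,1
M351,rheumatic_disease,1
B18,mild_liver_disease,2
K70,mild_liver_disease,2
K73,mild_liver_disease,2
K74,mild_liver_disease,2
K760,mild_liver_disease,2
Z944,mild_liver_disease,2
E102,diabetes_with_complication,1
E103,diabetes_with_complication,1
E104,diabetes_with_complication,1
E105,diabetes_with_complication,1
E107,diabetes_with_complication,1
E112,diabetes_with_complication,1
E113,diabetes_with_complication,1
E114,diabetes_with_complication,1
E115,diabetes_with_complication,1
E117,diabetes_with_complication,1
E142,diabetes_with_complication,1
E147,diabetes_with_complication,1
G041,hemiplegia_paraplegia,2
G114,hemiplegia_paraplegia,2
G81,hemiplegia_paraplegia,2
G82,hemiplegia_paraplegia,2
G830,hemiplegia_paraplegia,2
N18,renal_disease,1
N19,renal_disease,1
I120,renal_disease,1
I131,renal_disease,1
Z490,renal_disease,1
Z992,renal_disease,1
C18,any_malignancy,2
C34,any_malignancy,2
C43,any_malignancy,2
C50,any_malignancy,2
C61,any_malignancy,2
C81,any_malignancy,2
C90,any_malignancy,2
C92,any_malignancy,2
I850,moderate_severe_liver_disease,4
K704,moderate_severe_liver_disease,4
K721,moderate_severe_liver_disease,4
K729,moderate_severe_liver_disease,4
K766,moderate_severe_liver_disease,4
C77,metastatic_solid_tumour,6
C78,metastatic_solid_tumour,6
C79,metastatic_solid_tumour,6
C80,metastatic_solid_tumour,6
B20,hiv_aids,4
B21,hiv_aids,4
B22,hiv_aids,4
B24,hiv_aids,4
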