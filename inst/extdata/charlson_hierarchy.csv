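mild,severe
mild_liver_disease,moderate_severe_liver_disease
any_malignancy,metastatic_solid_tumour
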