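patient_id,before_au,after_au
PAT001,5.720,3.505
PAT003,2.213,1.988
PAT004,2.463,1.569
PAT005,2.228,1.839
PAT006,4.246,3.557
PAT007,1.982,1.840
PAT008,2.603,1.489
PAT009,52.637,20.038
PAT010,5.368,2.488
PAT011,2.213,2.023
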