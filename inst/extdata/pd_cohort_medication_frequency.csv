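patient_id,before_hz,after_hz
PAT001,4.888,3.447
PAT003,1.065,1.024
PAT004,2.087,1.027
PAT005,1.632,1.030
PAT006,1.054,1.027
PAT007,1.050,1.028
PAT008,1.638,1.217
PAT009,4.205,3.421
PAT010,1.462,1.025
PAT011,1.052,1.017
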