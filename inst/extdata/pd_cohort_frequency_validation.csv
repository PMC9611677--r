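patient_id,f_acc_hz,f_vid_hz
PAT001,4.877,4.888
PAT002,1.001,1.223
PAT003,1.467,1.065
PAT004,1.533,2.087
PAT005,1.334,1.632
PAT006,1.258,1.054
PAT007,1.034,1.050
PAT008,1.577,1.638
PAT009,4.002,4.205
PAT010,1.134,1.462
PAT011,NA,1.052
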