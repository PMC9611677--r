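patient_id,a_acc_cm_s2,a_vid_au
PAT001,14.251,5.720
PAT002,7.900,4.347
PAT003,12.589,2.213
PAT004,5.172,2.463
PAT005,4.782,2.228
PAT006,3.249,4.246
PAT007,6.259,1.982
PAT008,7.325,2.603
PAT009,202.873,52.637
PAT010,4.788,5.368
PAT011,NA,NA
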