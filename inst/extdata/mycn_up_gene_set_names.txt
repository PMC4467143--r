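COLLER_MYC_TARGETS_UP
DANG_MYC_TARGETS_UP
DANG_REGULATED_BY_MYC_UP
KIM_MYC_AMPLIFICATION_TARGETS_UP
LEE_LIVER_CANCER_MYC_UP
SCHUHMACHER_MYC_TARGETS_UP
YU_MYC_TARGETS_UP
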