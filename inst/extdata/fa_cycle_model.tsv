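reaction_id	equation	gpr	subsystem
ACC	accoa_c[c] + atp_c[b] + co2_c[b] => malcoa_c[c]	ACACA	fatty-acid synthesis
FAS	malcoa_c[c] + 2 nadph_c[b] => fachain_c[c] + co2_c[b] + coa_c[b]	FASN	fatty-acid synthesis
CSHUT	fachain_c[c] => fachain_m[m]	CPT1A and CPT2	carnitine shuttle
BOX	fachain_m[m] + coa_m[b] => accoa_m[m] + nadh_m[b] + fadh2_m[b]	HADHA	beta-oxidation
CS	accoa_m[m] + oaa_m[m] => cit_m[m] + coa_m[b]	CS	citrate synthesis
CMA	cit_m[m] + mal_c[c] <=> cit_c[c] + mal_m[m]	SLC25A1	citrate-malate antiport
ACL	cit_c[c] + atp_c[b] + coa_c[b] => accoa_c[c] + oaa_c[c]	ACLY	citrate lyase
MDHC	oaa_c[c] + nadh_c[b] => mal_c[c]	MDH1	malate shuttle
MDHM	mal_m[m] => oaa_m[m] + nadh_m[b]	MDH2	malate shuttle
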