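name	category	grade	E_lv_max	R_sys	C_art	V_total	T	note
normal	normal	N/A	2.5	0.994	1.75	5700	1	R stored as 0.994: the published 0.094 is inconsistent with every disease row and with MAP at CO 5 l/min; see package documentation
htn_stage1	hypertension	Stage 1	2.5	1.194	1.265	5700	1	
htn_stage2	hypertension	Stage 2	2.7	1.374	1.165	5700	1	
htn_accelerated	hypertension	Accelerated	2.7	1.614	1.165	5700	1	
hf_mild	heart_failure	Mild	2	1.094	1.75	5700	1	
hf_moderate	heart_failure	Moderate	1.4	1.094	1.65	5700	0.857	
hf_severe	heart_failure	Severe	0.8	1.194	1.55	5700	0.75	
haem_I	haemorrhage	Stage I	2.8	0.994	1.75	5200	0.6	
haem_II	haemorrhage	Stage II	3.2	1.034	1.7	4500	0.5	
haem_III	haemorrhage	Stage III	3	1.034	1.7	3700	0.429	
haem_IV	haemorrhage	Stage IV	3	1.018	1.7	2850	0.375	
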