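trial_id	subject_id	run_id	phase	onset	beat_condition	stimulation_delivered	source_category	word	novelty	response	source_truth	item_outcome	source_outcome
s01_r1_enc001	s01	s01_r1	encoding	0.5	monaural	TRUE	color	s01_r1_w001	na	none	source_a	remembered	forgotten
s01_r1_enc002	s01	s01_r1	encoding	5	monaural	TRUE	color	s01_r1_w002	na	none	source_a	remembered	remembered
s01_r1_enc003	s01	s01_r1	encoding	9.5	monaural	TRUE	color	s01_r1_w003	na	none	source_b	remembered	remembered
s01_r1_enc004	s01	s01_r1	encoding	14	monaural	TRUE	color	s01_r1_w004	na	none	source_b	forgotten	excluded
s01_r1_enc005	s01	s01_r1	encoding	18.5	monaural	TRUE	color	s01_r1_w005	na	none	source_b	remembered	remembered
s01_r1_enc006	s01	s01_r1	encoding	23	monaural	TRUE	color	s01_r1_w006	na	none	source_b	remembered	remembered
s01_r1_enc007	s01	s01_r1	encoding	27.5	monaural	TRUE	color	s01_r1_w007	na	none	source_a	remembered	forgotten
s01_r1_enc008	s01	s01_r1	encoding	32	monaural	TRUE	color	s01_r1_w008	na	none	source_b	remembered	remembered
s01_r1_enc009	s01	s01_r1	encoding	36.5	monaural	TRUE	color	s01_r1_w009	na	none	source_a	forgotten	excluded
s01_r1_enc010	s01	s01_r1	encoding	41	monaural	TRUE	color	s01_r1_w010	na	none	source_b	remembered	remembered
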