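id	label	n_ranks	rank_step	max_value	scale
H1	depressed mood	5	1	4	HDRS
H2	feelings of guilt	5	1	4	HDRS
H3	suicide	5	1	4	HDRS
H4	insomnia early	3	1	2	HDRS
H5	insomnia middle	3	1	2	HDRS
H6	insomnia late	3	1	2	HDRS
H7	work and activities	5	1	4	HDRS
H8	retardation	5	1	4	HDRS
H9	agitation	5	1	4	HDRS
H10	anxiety psychic	5	1	4	HDRS
H11	anxiety somatic	5	1	4	HDRS
H12	somatic symptoms gastrointestinal	3	1	2	HDRS
H13	somatic symptoms general	3	1	2	HDRS
H14	genital symptoms	3	1	2	HDRS
H15	hypochondriasis	5	1	4	HDRS
H16	weight loss	3	1	2	HDRS
H17	insight	3	1	2	HDRS
Y1	elevated mood	5	1	4	YMRS
Y2	increased motor activity-energy	5	1	4	YMRS
Y3	sexual interest	5	1	4	YMRS
Y4	sleep	5	1	4	YMRS
Y5	irritability	5	2	8	YMRS
Y6	speech (rate and amount)	5	2	8	YMRS
Y7	language-thought disorder	5	1	4	YMRS
Y8	content	5	2	8	YMRS
Y9	disruptive-aggressive behavior	5	2	8	YMRS
Y10	appearance	5	1	4	YMRS
Y11	insight	5	1	4	YMRS
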