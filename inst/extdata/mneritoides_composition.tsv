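region	A	C	G	T	AT	GC	at_skew	gc_skew
whole_genome	28.9	16.6	17.1	37.4	66.3	33.7	-0.129	0.012
cox1	26.0	17.3	19.3	37.4	63.3	36.7	-0.180	0.055
cox2	29.1	17.5	18.5	34.9	64.0	36.0	-0.091	0.028
atp8	30.2	15.7	15.1	39.0	69.2	30.8	-0.127	-0.019
atp6	24.9	17.1	15.5	42.5	67.4	32.6	-0.261	-0.049
rrnS	30.7	13.8	37.5	17.9	48.6	51.3	0.263	0.462
rrnL	36.1	12.5	36.4	15.0	51.1	48.9	0.413	0.489
nad1	25.7	16.8	17.1	40.4	66.1	33.9	-0.222	0.009
nad6	26.8	15.7	16.1	41.5	68.3	31.8	-0.215	0.013
cob	24.6	18.7	17.7	39.0	63.6	36.4	-0.226	-0.027
nad4l	27.9	15.8	17.2	39.1	67.0	33.0	-0.167	0.042
nad4	26.4	19.0	15.2	39.4	65.8	34.2	-0.198	-0.111
nad5	25.7	20.1	15.9	38.3	64.0	36.0	-0.197	-0.117
CR	32.7	19.8	15.8	31.6	64.3	35.7	0.016	-0.112
cox3	24.4	18.6	22.2	34.9	59.3	40.8	-0.177	0.088
nad3	28.2	15.0	19.5	37.3	65.5	34.5	-0.139	0.130
nad2	27.7	13.2	17.5	41.6	69.3	30.7	-0.201	0.140
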