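node_id	label	x	y	z	region_class
r_dacc	Right dorsal ACC	10	-2	45	ACC
r_pins	Right posterior insula	36	-9	14	insula
r_mins	Right mid insula	37	1	-4	insula
l_acc	Left ACC	-5	18	34	ACC
l_racc	Left rostral ACC	-11	45	8	ACC
r_racc	Right rostral ACC	12	36	20	ACC
l_ains	Left anterior insula	-35	20	0	insula
r_ains	Right anterior insula	36	22	3	insula
r_avins	Right anterior ventral insula	34	16	-8	insula
r_acc	Right ACC	10	22	27	ACC
l_damg	Left dorsal amygdala	-22	-4	-12	amygdala
r_damg	Right dorsal amygdala	22	-4	-12	amygdala
l_mamg	Left medial amygdala	-14	-4	-20	amygdala
r_mamg	Right medial amygdala	14	-4	-20	amygdala
l_vlamg	Left ventrolateral amygdala	-28	-4	-22	amygdala
r_vlamg	Right ventrolateral amygdala	28	-4	-22	amygdala
l_caud	Left caudate	-13	7	10	striatum
r_caud	Right caudate	14	8	11	striatum
l_nacc	Left nucleus accumbens	-10	12	-7	striatum
r_nacc	Right nucleus accumbens	10	10	-8	striatum
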