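species	location	mean_density	se
microdeutopus_obtusatus	H	10.0	3.1
microdeutopus_obtusatus	I	13.7	5.0
microdeutopus_obtusatus	L	5.3	3.2
athanas_nitescens	H	10.0	2.7
athanas_nitescens	I	7.2	1.3
athanas_nitescens	L	4.2	1.2
cymodoce_truncata	H	3.8	0.6
cymodoce_truncata	I	2.8	1.3
cymodoce_truncata	L	2.7	0.8
nontarget_pool	H	10.7	2.9
nontarget_pool	I	4.5	1.0
nontarget_pool	L	3.8	0.8
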