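rsid	chromosome	position	effect_allele	other_allele	beta	se	pvalue	cancer_type	smoking_related
rs000019	10	146761057	A	G	0.0270784352729505	0.015	0.071038851840052	breast	FALSE
rs000020	17	26762885	C	G	0.11771010601534	0.015	4.24952680096658e-15	breast	FALSE
rs000021	11	182339387	T	C	-0.202974686068078	0.015	1.01720584264773e-41	breast	FALSE
rs000022	4	153774374	A	G	0.297494730938985	0.015	1.54596815728658e-87	breast	FALSE
rs000023	7	185949181	G	T	0.185770755673914	0.015	3.16198134909591e-35	breast	FALSE
rs000024	15	206929778	A	T	0.180092609420908	0.015	3.29751182653863e-33	breast	FALSE
rs000025	3	200145449	C	G	0.134422482631971	0.015	3.20294566843592e-19	breast	FALSE
rs000026	15	122408841	G	A	0.0380534632611809	0.015	0.011183967808062	breast	FALSE
rs000027	20	157305332	G	C	0.0824400511287991	0.015	3.88495001616248e-08	breast	FALSE
rs000028	12	65738344	C	T	0.285505657652419	0.015	8.96725991217718e-81	breast	FALSE
rs000029	10	118774994	T	A	0.216680042128549	0.015	2.68245409516182e-47	breast	FALSE
rs000030	10	26826651	T	C	0.0172943637203881	0.015	0.248927795751248	breast	FALSE
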