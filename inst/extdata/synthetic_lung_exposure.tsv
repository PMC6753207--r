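rsid	chromosome	position	effect_allele	other_allele	beta	se	pvalue	cancer_type	smoking_related
rs000001	7	2435801	T	A	-0.0489054735773078	0.015	0.00111268959480644	lung	TRUE
rs000002	20	135636729	C	T	0.0828692783128708	0.015	3.30202208844958e-08	lung	TRUE
rs000003	17	148008826	A	G	-0.101241576593375	0.015	1.48418464539217e-11	lung	TRUE
rs000004	8	106329467	A	G	0.0321539188565138	0.015	0.0320653846070684	lung	TRUE
rs000005	20	163789388	T	C	0.0466153825970404	0.015	0.00188554352106798	lung	TRUE
rs000006	10	236307811	C	G	0.176094943134405	0.015	7.98039243463964e-32	lung	TRUE
rs000007	4	181133708	T	C	0.0928184783438952	0.015	6.09715426405436e-10	lung	TRUE
rs000008	4	130986181	A	C	-0.0169101472131322	0.015	0.259597426231938	lung	TRUE
rs000009	19	233475951	C	T	0.137554243426907	0.015	4.71779302596609e-20	lung	TRUE
rs000010	9	234291154	T	C	-0.0334889046940894	0.015	0.0255757534827722	lung	TRUE
rs000011	12	185853764	C	G	0.0789672148310464	0.015	1.40585945832543e-07	lung	TRUE
rs000012	21	180001081	A	G	-0.119226665312258	0.015	1.88868140188206e-15	lung	TRUE
rs000013	13	9223723	T	G	0.214163331702455	0.015	3.0201078867725e-46	lung	TRUE
rs000014	18	155385095	A	C	-0.22002295412452	0.015	1.03047070267349e-48	lung	TRUE
rs000015	7	66572815	T	G	-0.0355025067904344	0.015	0.0179409881646415	lung	TRUE
rs000016	5	9612272	C	A	-0.0290006947496251	0.015	0.0531894462739546	lung	TRUE
rs000017	8	139576102	G	T	-0.127463211050079	0.015	1.93638433999248e-17	lung	TRUE
rs000018	21	209731598	C	T	0.01	0.015	0.504985075093846	lung	TRUE
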