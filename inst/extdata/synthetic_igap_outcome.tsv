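MarkerName	Chromosome	Position	Effect_allele	Non_Effect_allele	Beta	SE	P
rs000001	7	2435801	T	A	-0.0117410986745804	0.02	0.557166813209331
rs000002	20	135636729	T	C	0.0488216142577709	0.02	0.0146433815674762
rs000004	8	106329467	G	A	-0.0111379841481065	0.02	0.577596296190005
rs000006	10	236307811	G	C	0.0458860689358757	0.02	0.0217730747351855
rs000007	4	181133708	C	T	-0.00613494269740691	0.02	0.759035849710925
rs000008	4	130986181	C	A	0.0266129961464747	0.02	0.183304265658345
rs000009	19	233475951	C	T	-0.00363148204143918	0.02	0.855916974520532
rs000010	9	234291154	T	C	0.000771959202562309	0.02	0.969210928664417
rs000011	12	185853764	C	G	0.00189732754864283	0.02	0.924420962960808
rs000012	21	180001081	A	G	0.0212070591054076	0.02	0.288984056153987
rs000013	13	9223723	T	G	-0.00229914531987548	0.02	0.908478994210077
rs000014	18	155385095	A	C	0.0263335542310281	0.02	0.187946677721242
rs000015	7	66572815	G	T	-0.0235055805446229	0.02	0.239883102344933
rs000016	5	9612272	C	A	-0.0387270545845006	0.02	0.0528245148153659
rs000017	8	139576102	G	T	0.0358182097173762	0.02	0.0733076607206428
rs000018	21	209731598	C	T	-0.0154305911621119	0.02	0.440393109307122
rs000019	10	146761057	A	G	-0.0142205707222043	0.02	0.477066552723205
rs000020	17	26762885	G	C	0.0326731349390192	0.02	0.102330945186361
rs000021	11	182339387	T	C	0.00800273770580291	0.02	0.689055698009799
rs000022	4	153774374	G	A	0.023617371989653	0.02	0.237654927129727
rs000023	7	185949181	T	G	0.0429775061237841	0.02	0.0316442857849236
rs000024	15	206929778	A	T	0.0239451833067754	0.02	0.231205555280031
rs000025	3	200145449	C	G	-0.0418836693439775	0.02	0.0362436399500284
rs000026	15	122408841	G	A	0.00826831644814533	0.02	0.679301984166982
rs000027	20	157305332	G	C	0.00995083968331855	0.02	0.618806904000517
rs000028	12	65738344	T	C	0.0218713155414496	0.02	0.274145465640359
rs000029	10	118774994	T	A	-0.0397912886993453	0.02	0.0466389371870475
rs000030	10	26826651	T	C	-0.0206979080123248	0.02	0.300717762836495
rs900001	17	148009638	A	G	-0.00627304856043242	0.02	0.753785035562756
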