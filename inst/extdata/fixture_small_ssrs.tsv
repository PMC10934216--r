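ID	SSR nr.	type	SSR	size	start	end	aln_start	aln_end	at_edge
P015_WE12|L5	1	p2	(AG)8	16	260	275	266	281	FALSE
P015_WE12|L8	1	p3	(AAG)6	18	276	293	280	297	FALSE
P015_WE12|L9	1	p1	(T)12	12	214	225	222	233	FALSE
P015_WH11|L10	1	p3	(GAT)5	15	230	244	235	249	FALSE
P015_WH11|L2	1	p2	(AC)6	12	273	284	281	292	FALSE
P015_WH11|L4	1	p4	(GCAT)3	12	155	166	157	168	FALSE
P015_WH11|L8	1	p3	(AAG)4	12	1	12	286	297	TRUE
P028_WD08|L10	1	p3	(GAT)5	15	230	244	235	249	FALSE
P028_WD08|L2	1	p2	(AC)9	18	277	294	281	298	FALSE
P03_WA06|L1	1	c	(GTAT)3	12	277	288	279	290	FALSE
P03_WA06|L1	2	c	(GT)12	24	289	312	291	314	FALSE
P03_WA06|L4	1	p4	(GCAT)3	12	151	162	157	168	FALSE
P072_WC08|L1	1	c	(GTAT)3	12	271	282	279	290	FALSE
P072_WC08|L1	2	c	(GT)12	24	283	306	291	314	FALSE
P072_WC08|L4	1	p4	(GCAT)3	12	154	165	157	168	FALSE
P072_WC08|L9	1	p1	(T)14	14	220	233	222	235	FALSE
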