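group_id	locus_id	aln_start	aln_end	class	motifs	n_members	any_truncated	category	tier	n_samples	n_distinct_repeat_counts	edge_artifact
L1|ATGT|g1	L1	279	290	4	GTAT	2	FALSE	shared	across_genera	2	1	FALSE
L1|GT|g1	L1	291	314	2	GT	2	FALSE	shared	across_genera	2	1	FALSE
L10|ATG|g1	L10	235	249	3	GAT	2	FALSE	shared	within_species	2	1	FALSE
L2|AC|g1	L2	281	298	2	AC	2	FALSE	polymorphic	within_species	2	2	FALSE
L4|ATGC|g1	L4	157	168	4	GCAT	3	FALSE	shared	across_genera	3	1	FALSE
L5|AG|g1	L5	266	281	2	AG	1	FALSE	unique	not_applicable	1	1	FALSE
L8|AAG|g1	L8	280	297	3	AAG	2	TRUE	polymorphic	within_genus	2	2	TRUE
L9|T|g1	L9	222	235	1	T	2	FALSE	polymorphic	across_genera	2	2	FALSE
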