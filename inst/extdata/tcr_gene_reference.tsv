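# tcrpair curated human TR gene reference, table version 1.0
# Curated subset of human TRAV/TRAJ/TRBV/TRBJ gene names with IMGT-style
# functionality calls (F = functional, ORF = open reading frame, P = pseudogene).
# Schema: locus <TAB> gene <TAB> functionality
locus	gene	functionality
TRBV	TRBV1	P
TRBV	TRBV2	F
TRBV	TRBV3-1	F
TRBV	TRBV4-1	F
TRBV	TRBV4-2	F
TRBV	TRBV4-3	F
TRBV	TRBV5-1	F
TRBV	TRBV5-2	P
TRBV	TRBV5-4	F
TRBV	TRBV5-5	F
TRBV	TRBV5-6	F
TRBV	TRBV5-8	F
TRBV	TRBV6-1	F
TRBV	TRBV6-2	F
TRBV	TRBV6-3	F
TRBV	TRBV6-4	F
TRBV	TRBV6-5	F
TRBV	TRBV6-6	F
TRBV	TRBV6-8	F
TRBV	TRBV6-9	F
TRBV	TRBV7-1	P
TRBV	TRBV7-2	F
TRBV	TRBV7-3	F
TRBV	TRBV7-4	F
TRBV	TRBV7-5	P
TRBV	TRBV7-6	F
TRBV	TRBV7-7	F
TRBV	TRBV7-8	F
TRBV	TRBV7-9	F
TRBV	TRBV9	F
TRBV	TRBV10-1	F
TRBV	TRBV10-2	F
TRBV	TRBV10-3	F
TRBV	TRBV11-1	F
TRBV	TRBV11-2	F
TRBV	TRBV11-3	F
TRBV	TRBV12-1	P
TRBV	TRBV12-2	P
TRBV	TRBV12-3	F
TRBV	TRBV12-4	F
TRBV	TRBV12-5	F
TRBV	TRBV13	F
TRBV	TRBV14	F
TRBV	TRBV15	F
TRBV	TRBV16	F
TRBV	TRBV17	ORF
TRBV	TRBV18	F
TRBV	TRBV19	F
TRBV	TRBV20-1	F
TRBV	TRBV21-1	P
TRBV	TRBV22-1	P
TRBV	TRBV23-1	ORF
TRBV	TRBV24-1	F
TRBV	TRBV25-1	F
TRBV	TRBV26	P
TRBV	TRBV27	F
TRBV	TRBV28	F
TRBV	TRBV29-1	F
TRBV	TRBV30	F
TRBJ	TRBJ1-1	F
TRBJ	TRBJ1-2	F
TRBJ	TRBJ1-3	F
TRBJ	TRBJ1-4	F
TRBJ	TRBJ1-5	F
TRBJ	TRBJ1-6	F
TRBJ	TRBJ2-1	F
TRBJ	TRBJ2-2	F
TRBJ	TRBJ2-2P	P
TRBJ	TRBJ2-3	F
TRBJ	TRBJ2-4	F
TRBJ	TRBJ2-5	F
TRBJ	TRBJ2-6	F
TRBJ	TRBJ2-7	F
TRAV	TRAV1-1	F
TRAV	TRAV1-2	F
TRAV	TRAV2	F
TRAV	TRAV3	F
TRAV	TRAV4	F
TRAV	TRAV5	F
TRAV	TRAV6	F
TRAV	TRAV7	F
TRAV	TRAV8-1	F
TRAV	TRAV8-2	F
TRAV	TRAV8-3	F
TRAV	TRAV8-4	F
TRAV	TRAV8-5	P
TRAV	TRAV8-6	F
TRAV	TRAV8-7	ORF
TRAV	TRAV9-1	F
TRAV	TRAV9-2	F
TRAV	TRAV10	F
TRAV	TRAV11	P
TRAV	TRAV12-1	F
TRAV	TRAV12-2	F
TRAV	TRAV12-3	F
TRAV	TRAV13-1	F
TRAV	TRAV13-2	F
TRAV	TRAV15	P
TRAV	TRAV16	F
TRAV	TRAV17	F
TRAV	TRAV18	F
TRAV	TRAV19	F
TRAV	TRAV20	F
TRAV	TRAV21	F
TRAV	TRAV22	F
TRAV	TRAV23	F
TRAV	TRAV24	F
TRAV	TRAV25	F
TRAV	TRAV26-1	F
TRAV	TRAV26-2	F
TRAV	TRAV27	F
TRAV	TRAV28	P
TRAV	TRAV29	F
TRAV	TRAV30	F
TRAV	TRAV31	P
TRAV	TRAV32	P
TRAV	TRAV33	P
TRAV	TRAV34	F
TRAV	TRAV35	F
TRAV	TRAV36	F
TRAV	TRAV37	P
TRAV	TRAV38-1	F
TRAV	TRAV38-2	F
TRAV	TRAV39	F
TRAV	TRAV40	F
TRAV	TRAV41	F
TRAJ	TRAJ1	ORF
TRAJ	TRAJ2	P
TRAJ	TRAJ3	F
TRAJ	TRAJ4	F
TRAJ	TRAJ5	F
TRAJ	TRAJ6	F
TRAJ	TRAJ7	F
TRAJ	TRAJ8	F
TRAJ	TRAJ9	F
TRAJ	TRAJ10	F
TRAJ	TRAJ11	F
TRAJ	TRAJ12	F
TRAJ	TRAJ13	F
TRAJ	TRAJ14	F
TRAJ	TRAJ15	F
TRAJ	TRAJ16	F
TRAJ	TRAJ17	F
TRAJ	TRAJ18	F
TRAJ	TRAJ19	ORF
TRAJ	TRAJ20	F
TRAJ	TRAJ21	F
TRAJ	TRAJ22	F
TRAJ	TRAJ23	F
TRAJ	TRAJ24	F
TRAJ	TRAJ25	ORF
TRAJ	TRAJ26	F
TRAJ	TRAJ27	F
TRAJ	TRAJ28	F
TRAJ	TRAJ29	F
TRAJ	TRAJ30	F
TRAJ	TRAJ31	F
TRAJ	TRAJ32	F
TRAJ	TRAJ33	F
TRAJ	TRAJ34	F
TRAJ	TRAJ35	ORF
TRAJ	TRAJ36	F
TRAJ	TRAJ37	F
TRAJ	TRAJ38	F
TRAJ	TRAJ39	F
TRAJ	TRAJ40	F
TRAJ	TRAJ41	F
TRAJ	TRAJ42	F
TRAJ	TRAJ43	F
TRAJ	TRAJ44	F
TRAJ	TRAJ45	F
TRAJ	TRAJ46	F
TRAJ	TRAJ47	F
TRAJ	TRAJ48	F
TRAJ	TRAJ49	F
TRAJ	TRAJ50	F
TRAJ	TRAJ52	F
TRAJ	TRAJ53	F
TRAJ	TRAJ54	F
TRAJ	TRAJ56	F
TRAJ	TRAJ57	F
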