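# SYNTHETIC cohort (not patient data): segment calls emulating a genetically
# heterogeneous ALL with breakpoint-distinct chromosome 9 deletions, a
# hom-del and a cnLOH second hit, nested chromosome 14 deletions and a
# chromosome X amplification, observed across a diagnostic sample and
# serially transplanted mice. Derived by hand from a 6-clone truth tree.
sample	chrom	start	end	class	zygosity	status
DX	14	50000000	52000000	DEL	het	clonal
DX	9	21000000	22500000	DEL	het	subclonal
DX	14	50400000	51200000	DEL	het	subclonal
DX	9	20800000	22600000	DEL	het	subclonal
DX	X	10000000	15000000	AMP	na	subclonal
P1	14	50000000	52000000	DEL	het	clonal
P1	9	21000000	22500000	DEL	het	clonal
P1	14	50400000	51200000	DEL	het	clonal
P1	9	21200000	22300000	DEL	hom	subclonal
S1	14	50000000	52000000	DEL	het	clonal
S1	9	21000000	22500000	DEL	het	clonal
S1	14	50400000	51200000	DEL	het	clonal
S1	9	21200000	22300000	DEL	hom	clonal
S2	14	50000000	52000000	DEL	het	clonal
S2	9	21000000	22500000	DEL	het	clonal
S2	9	21100000	22400000	CNLOH	cnloh	subclonal
P2	14	50000000	52000000	DEL	het	clonal
P2	9	20800000	22600000	DEL	het	clonal
P2	X	10000000	15000000	AMP	na	subclonal
S3	14	50000000	52000000	DEL	het	clonal
S3	9	20800000	22600000	DEL	het	clonal
S3	X	10000000	15000000	AMP	na	clonal
P3	14	50000000	52000000	DEL	het	clonal
P3	9	21000000	22500000	DEL	het	subclonal
P3	9	20800000	22600000	DEL	het	subclonal
P3	X	10000000	15000000	AMP	na	subclonal
S4	14	50000000	52000000	DEL	het	clonal
S4	9	21000000	22500000	DEL	het	clonal
S4	14	50400000	51200000	DEL	het	subclonal
S4	9	21200000	22300000	DEL	hom	subclonal
S5	14	50000000	52000000	DEL	het	clonal
S5	9	21000000	22500000	DEL	het	clonal
S5	9	21100000	22400000	CNLOH	cnloh	clonal
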