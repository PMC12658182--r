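# SYNTHETIC sample manifest matching patient2_synthetic_segments.tsv.
# P4 is flagged unassayed (insufficient cells); its secondary S5 is assayed.
sample_id	patient	timepoint	compartment	host	parent_sample	assayed
DX	PT2	diagnosis	bulk	patient	NA	TRUE
P1	PT2	diagnosis	bulk	primary	DX	TRUE
P2	PT2	diagnosis	bulk	primary	DX	TRUE
P3	PT2	diagnosis	bulk	primary	DX	TRUE
P4	PT2	diagnosis	bulk	primary	DX	FALSE
S1	PT2	diagnosis	bulk	secondary	P1	TRUE
S2	PT2	diagnosis	bulk	secondary	P1	TRUE
S3	PT2	diagnosis	bulk	secondary	P2	TRUE
S4	PT2	diagnosis	bulk	secondary	P3	TRUE
S5	PT2	diagnosis	bulk	secondary	P4	TRUE
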