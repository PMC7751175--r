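sequence_id	group
REF	reference
focal_nonC4	non-C4
nonC4_1	non-C4
nonC4_2	non-C4
nonC4_3	non-C4
weak_1	weak-C4
weak_2	weak-C4
focal_C4	C4
C4_1	C4
C4_2	C4
C4_3	C4
C4_4	C4
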