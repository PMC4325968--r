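region	channel
1	FP1-F7
1	F7-T7
1	FP1-F3
1	F3-C3
1	T7-FT9
2	FP2-F4
2	F4-C4
2	FP2-F8
2	F8-T8
2	FT10-T8
3	T7-P7
3	P7-O1
3	C3-P3
3	P3-O1
4	C4-P4
4	P4-O2
4	T8-P8
4	P8-O2
5	FZ-CZ
5	CZ-PZ
5	FT9-FT10
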