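ID	snp1	snp2	snp3	snp4	snp5	snp6	snp7	snp8
1	AG	CC	CC	GG	CT	GG	AA	CC
2	AG	CC	CC	GG	TT	GG	AA	CC
3	AA	CC	CC	GG	TT	GG	AA	CC
4	AG	CT	CT	AG	CT	AG	AG	CT
5	GG	CT	CT	AG	CC	GG	AA	CC
6	AA	CC	CC	GG	TT	GG	AA	CC
7	AG	CT	CT	AG	CT	AG	AG	CT
8	AA	CC	CC	GG	TT	GG	AA	CC
9	GG	CT	TT	AG	CC	AG	AA	CC
10	AG	CT	CT	GG	CT	AG	AA	CC
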