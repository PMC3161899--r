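id	length	optimum	sequence
S1	20	-9	1H 1P 1H 2P 2H 1P 1H 2P 1H 1P 2H 2P 1H 1P 1H
S2	24	-9	2H 2P 1H 2P 1H 2P 1H 2P 1H 2P 1H 2P 1H 2P 2H
S3	25	-8	2P 1H 2P 2H 4P 2H 4P 2H 4P 2H
S4	36	-14	3P 2H 2P 2H 5P 7H 2P 2H 4P 2H 2P 1H 2P
S5	48	-23	2P 1H 2P 2H 2P 2H 5P 10H 6P 2H 2P 2H 2P 1H 2P 5H
S6	50	-21	2H 1P 1H 1P 1H 1P 1H 1P 4H 1P 1H 3P 1H 3P 1H 4P 1H3P 1H 3P 1H 1P 4H 1P 1H 1P 1H 1P 1H 1P 1H 1H
S7	60	-36	2P 3H 1P 8H 3P 10H 1P 1H 3P 12H 4P 6H 1P 2H 1P 1H 1P
S8	64	-42	12H 1P 1H 1P 1H 2P 2H 2P 2H 2P 1H 2P 2H 2P 2H2P 1H 2P 2H 2P 2H 2P 1H 1P 1H 1P 12H
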