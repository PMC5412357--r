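arm	stem_start5	stem_end5	stem_start3	stem_end3	loop_start	loop_end
acceptor	1	7	66	72	NA	NA
DHU	10	13	22	25	14	21
anticodon	27	31	39	43	32	38
TPsiC	49	53	61	65	54	60
extra	NA	NA	NA	NA	44	48
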