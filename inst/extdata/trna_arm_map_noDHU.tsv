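arm	stem_start5	stem_end5	stem_start3	stem_end3	loop_start	loop_end
acceptor	1	7	55	61	NA	NA
DHU	NA	NA	NA	NA	10	15
anticodon	16	20	28	32	21	27
TPsiC	38	42	50	54	43	49
extra	NA	NA	NA	NA	33	37
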