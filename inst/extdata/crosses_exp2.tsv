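# X-chromosome nondisjunction assay, experiment 2: catalytic-dead OsSPO11D
# (Y213F) and the DmSPO11 rescue control alongside the no-transgene control.
label	mothers	total_progeny	n_x0_sons	n_xxy_daughters
none	55	1245	119	88
OsSPO11D-Y213F	57	1994	175	129
mei-W68+	22	3434	3	3
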