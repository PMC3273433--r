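# Female fertility assay: eggs laid and pupae generated per genotype.
# Fertility = pupae / eggs. het = mei-W68^1 heterozygote (SPO11-proficient);
# hom = mei-W68^1 homozygote (SPO11-deficient), with the named transgene.
label	mothers	eggs	pupae
het-none	37	3768	3309
hom-none	107	6109	1568
hom-DmSPO11	11	1207	1047
hom-AtSPO11-1	40	2880	691
hom-AtSPO11-2	20	1536	359
hom-OsSPO11D	60	3577	753
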