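# Oocyte-nucleus cytology in the DSB-repair-deficient (mus301) background:
# gamma-H2Av DSB foci scored in stage 2-8 egg chambers, defective (non-disc)
# karyosome morphology in stage 3-8. 'het' = SPO11-proficient positive
# control; 'none' = SPO11-deficient, no transgene (negative control).
# Ovary counts for the DmSPO11 karyosome row are not published; 2 is assumed
# (metadata only, unused by any statistic).
label	endpoint	stage_range	n_positive	n_total	ovaries
het	dsb_signal	2-8	344	345	3
none	dsb_signal	2-8	16	220	2
DmSPO11	dsb_signal	2-8	180	180	2
het	karyosome_defect	3-8	254	278	3
none	karyosome_defect	3-8	2	177	2
DmSPO11	karyosome_defect	3-8	93	132	2
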