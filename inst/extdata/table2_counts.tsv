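# Per-panel species and isolate counts for the four-medium water study
# (CH = CHROMagar Candida, DG = DG18, DR = DRBC, SY = SYMPHONY).
# Species denominator: 152 taxa identified by the full panel.
# Isolate denominator: 2479 analysed isolates (identified + lost + unknown);
# the full-panel isolate count (2389) is the identified-only figure.
# taxa_total=152
# isolates_total=2479
panel	size	species_count	isolate_count
DG	1	73	556
CH	1	91	659
SY	1	97	565
DR	1	97	699
CH + DG	2	107	1215
DG + SY	2	115	1121
DG + DR	2	117	1255
CH + SY	2	122	1224
DR + SY	2	125	1264
CH + DR	2	126	1358
CH + DG + SY	3	133	1780
CH + DG + DR	3	136	1914
DG + DR + SY	3	138	1820
CH + DR + SY	3	144	1923
CH + DG + DR + SY	4	152	2389
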