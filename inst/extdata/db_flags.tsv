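# Reference-database membership flags for the 30 most common taxa of the
# study, with strain counts per medium (n = distinct strains, n_i = isolates).
# Flag transcription convention for the printed dot columns: three dots ->
# initial MSI-2 + supplemented MSI-2 + Bruker; two dots -> initial +
# supplemented, unless spectra for the species were added during the study
# (added_spectra = 1, hence absent from the initial database) -> supplemented
# + Bruker; one dot -> supplemented MSI-2 if added during the study, else
# Bruker. Membership of ambiguous one/two-dot rows is therefore a patterned
# reconstruction, not an authoritative transcription.
taxon	n_strains	ch	dg	dr	sy	n_isolates	msi2_initial	msi2_supplemented	bruker	added_spectra
Pichia fermentans	103	62	30	57	48	246	1	1	1	0
Metschnikowia pulcherrima	90	42	64	36	43	243	1	1	1	0
Hanseniaspora uvarum	84	40	51	61	47	226	1	1	1	0
Rhodotorula mucilaginosa	72	28	28	26	28	119	1	1	1	0
Candida pseudolambica	57	29	22	7	25	87	0	1	0	1
Saccharomyces cerevisiae	52	23	17	25	21	93	1	1	1	0
Pichia kudriavzevii	51	23	15	16	13	77	1	1	1	0
Nakazawaea holstii	47	19	9	23	19	80	1	1	0	0
Wickerhamomyces anomalus	42	11	18	18	12	66	1	1	1	0
Nakaseomyces glabratus	42	13	12	17	17	65	1	1	1	0
Debaryomyces hansenii	41	4	32	3	8	52	1	1	1	0
Nakazawaea wyomingensis	36	7	10	16	10	52	0	0	1	0
Clavispora lusitaniae	35	9	10	15	11	48	1	1	1	0
Pichia kluyveri	35	15	9	7	11	43	1	1	0	0
Saturnispora silvae	31	9	6	16	13	47	0	0	1	0
Diutina catenulata	25	16	4	7	5	35	1	1	1	0
Candida baotianensis	24	12	9	11	7	43	0	1	0	1
Lachancea kluyveri	24	9	6	9	8	33	0	0	1	0
Candida sake	23	12	6	3	5	27	0	1	1	1
Barnettozyma californica	20	7	6	8	5	27	0	0	1	0
Meyerozyma guilliermondii	20	9	3	8	3	23	1	1	1	0
Saturnispora dispora	17	11	4	9	4	33	0	0	1	0
Geotrichum sp.	17	14	1	3	2	21	0	0	1	0
Candida albicans	17	7	6	5	2	20	1	1	1	0
Candida solani	16	5	1	7	7	20	0	1	1	1
Candida railensis	15	4	4	5	3	16	0	1	0	1
Yamadazyma scolyti	14	5	3	7	2	18	0	0	1	0
Candida palmioleophila	14	5	6	4	2	17	1	1	1	0
Papiliotrema laurentii	14	11	1	0	3	17	1	1	1	0
Kluyveromyces dobzhanskii	13	7	5	4	3	23	0	0	1	0
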