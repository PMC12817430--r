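# Per-population seeding evidence for the 31-population Swiss survey,
# transcribed from the published summary table of non-genomic and genomic
# evidence; the 14 populations without any evidence line carry a single
# autochthonous source and no flags.
# SYNTHETIC fields: lat/lon are placeholder coordinates (the published table
# prints none; classification never uses them), and for admixed populations
# the per-ESU allochthonous_sources entries are inferred from the narrative
# (the table marks allochthony only at population level).
# Columns: pop_id lat lon sources source_kinds allochthonous_sources admixed
#          homogeneous_evidence collector_flag habitat_years
pop_id	lat	lon	sources	source_kinds	allochthonous_sources	admixed	homogeneous_evidence	collector_flag	habitat_years
1	47.45	9.55	Western Europe	homogeneous	Western Europe	1	1	0	2013
2	46.20	6.15	Western Europe	homogeneous		0	0	0
3	47.05	6.75	Western Europe	homogeneous		0	0	0
4	47.20	7.55	Swiss Plateau	homogeneous		0	0	1
5	47.00	8.30	Swiss Plateau,Western Europe,Central Europe	admixture_component,admixture_component,admixture_component	Western Europe,Central Europe	1	0	0
6	46.85	6.95	Swiss Plateau	homogeneous		0	0	0
7	47.10	7.25	Swiss Plateau	homogeneous		0	1	1	1998-2004
8	47.35	8.05	Swiss Plateau	homogeneous		0	1	1
9	47.40	8.55	Swiss Plateau	homogeneous		0	1	1	2002-2005
10	47.25	8.80	Swiss Plateau	homogeneous		0	1	1
11	47.50	8.75	Swiss Plateau	homogeneous		0	1	1	2010-2013
12	47.15	9.05	Swiss Plateau,Western Europe	admixture_component,admixture_component	Western Europe	1	1	1	2016-2019
13	47.30	7.85	Swiss Plateau	homogeneous		0	1	1	2019-2021
14	46.95	7.45	Swiss Plateau,Central Europe	admixture_component,admixture_component	Central Europe	1	1	0
15	47.05	9.45	Swiss Plateau,Central Europe	homogeneous,homogeneous	Central Europe	1	1	0
16	47.45	7.65	Swiss Plateau	homogeneous		0	1	1	2005-2008
17	46.75	9.65	Central Europe,Swiss Plateau,Western Europe	admixture_component,admixture_component,admixture_component	Central Europe,Western Europe	1	0	1	1993-1998
18	46.30	7.85	Southern Switzerland	homogeneous		0	0	0
19	47.55	8.90	Eastern Europe	homogeneous	Eastern Europe	0	1	0
20	47.60	9.15	Eastern Europe	homogeneous	Eastern Europe	0	1	1	2017-2020
21	46.15	8.95	Southern Switzerland	homogeneous		0	0	0
22	46.35	8.95	Southern Switzerland	homogeneous		0	0	0
23	46.50	9.85	Central Europe	homogeneous		0	0	0
24	46.55	7.95	Southern Switzerland,Swiss Plateau	admixture_component,admixture_component		1	0	0
25	46.25	7.35	Southern Switzerland	homogeneous		0	0	0
26	46.40	6.90	Western Europe	homogeneous		0	0	0
27	46.65	10.15	Central Europe	homogeneous		0	0	0
28	46.45	9.35	Southern Switzerland	homogeneous		0	0	0
29	47.00	6.60	Western Europe	homogeneous		0	0	0
30	46.60	8.60	Southern Switzerland	homogeneous		0	0	0
31	46.90	9.90	Central Europe	homogeneous		0	0	0
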