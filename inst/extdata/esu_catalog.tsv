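# Regional ESU catalog for the Swiss survey: four ESUs occur naturally in
# the region (rows with a natural, non-admixed reference population), one
# (Eastern Europe) is present only through introduced seed and has no
# in-region reference population, and the Italy ESU occurs in the species
# range but not in the region. Reference-population coordinates are
# SYNTHETIC placeholders matching table2_evidence.tsv.
# Columns: esu pop_id lat lon
esu	pop_id	lat	lon
Swiss Plateau	4	47.20	7.55
Swiss Plateau	6	46.85	6.95
Western Europe	2	46.20	6.15
Western Europe	3	47.05	6.75
Western Europe	26	46.40	6.90
Western Europe	29	47.00	6.60
Central Europe	23	46.50	9.85
Central Europe	27	46.65	10.15
Central Europe	31	46.90	9.90
Southern Switzerland	18	46.30	7.85
Southern Switzerland	21	46.15	8.95
Southern Switzerland	22	46.35	8.95
Southern Switzerland	25	46.25	7.35
Southern Switzerland	28	46.45	9.35
Southern Switzerland	30	46.60	8.60
Eastern Europe
Italy
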