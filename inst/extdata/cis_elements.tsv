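name	iupac_pattern	category	hormone_subclass
TE2F2NTPCNA	ATTCCCGC	growth_development	-
EBOX	CANNTG	growth_development	-
RYREPEAT4	CATGCA	growth_development	-
RAV1AAT	CAACA	growth_development	-
POLLEN1LEAAT52	AGAAA	growth_development	-
GT1CONSENSUS	GRWAAW	light	-
GATABOX	GATA	light	-
GBOXLERBCS	MCACGTGGC	light	-
BOXII	ATAGAA	light	-
IBOXCORE	GATAA	light	-
DPBFCOREDCD3	ACACNNG	hormone	abscisic_acid
ARFAT	TGTCTC	hormone	auxin
ARR1AT	NGATT	hormone	cytokinin
ERELEE4	AWTTCAAA	hormone	ethylene
GARE10OSREP1	TAACAGA	hormone	gibberellin
TGBOX	AACGTG	hormone	jasmonate
DRE2COREZMRAB17	ACCGAC	stress	-
ASF1MOTIFCAMV	TGACG	stress	-
BIHD1OS	TGTCA	stress	-
CBFHV	RYCGAC	stress	-
CGGBOX	CGGC	stress	-
GCCCORE	GCCGCC	stress	-
LTRECOREATCOR15	CCGAC	stress	-
MYBCORE	CNGTTR	stress	-
MYCCONSENSUSAT	CANNTG	stress	-
WRKY71OS	TGAC	stress	-
WBOXNTERF3	TGACY	stress	-
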