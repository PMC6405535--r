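# Restriction-enzyme panel backing the consolidated five-species COI
# PCR-RFLP key.
# Format: name<TAB>site. '^' marks the top-strand cut inside the recognition
# site (bottom-strand cut symmetric); (a/b) gives top/bottom cut offsets in
# bases past the 3' end of the recognition site (downstream cutters).
#
# BseJI and BsaBI are isoschizomers (same site, same blunt cut).
#
# Bco5I and AquVI are uncommon trade names whose recognition sequences are
# not published alongside the key this panel supports. The motifs below are
# SYNTHETIC PLACEHOLDER definitions: non-degenerate, non-palindromic, blunt,
# chosen not to interact with the rest of the panel. Fixtures generated by
# this package plant these motifs, so all predicted fragment lengths are
# internally consistent -- but do not use these two entries to predict
# digests of empirical sequences.
BseJI	GATNN^NNATC
BsaI	GGTCTC(1/5)
BsaBI	GATNN^NNATC
BpuEI	CTTGAG(16/14)
Bco5I	CCT^AAG
AquVI	GGT^ACG
BseRI	GAGGAG(10/8)
Eco130I	C^CWWGG
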