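# ALTERNATE 698 bp column-to-enzyme mapping of the consolidated key (the
# other reading of the garbled published header): assulta's second cut
# pattern under BsaI and zea's 584+114 under BsaBI.
#
# CAUTION: under this mapping no physical sequence can realize the zea row
# (BsaBI and BseJI are isoschizomers, so a BsaBI cut at 584 implies a BseJI
# cut there too, contradicting zea's uncut BseJI cell). It is provided for
# classification of externally supplied patterns only; the fixture
# generator refuses it. The coi3p_511 region is identical in both mappings.
species	region	region_length	enzyme	fragments
punctigera	coi5p_698	698	BseJI	698
punctigera	coi5p_698	698	BpuEI	494,204
punctigera	coi5p_698	698	BsaBI	698
punctigera	coi5p_698	698	BsaI	698
armigera	coi5p_698	698	BseJI	698
armigera	coi5p_698	698	BpuEI	698
armigera	coi5p_698	698	BsaBI	698
armigera	coi5p_698	698	BsaI	698
assulta	coi5p_698	698	BseJI	461,237
assulta	coi5p_698	698	BpuEI	698
assulta	coi5p_698	698	BsaBI	698
assulta	coi5p_698	698	BsaI	461,237
zea	coi5p_698	698	BseJI	698
zea	coi5p_698	698	BpuEI	698
zea	coi5p_698	698	BsaBI	584,114
zea	coi5p_698	698	BsaI	698
gelotopoeon	coi5p_698	698	BseJI	698
gelotopoeon	coi5p_698	698	BpuEI	698
gelotopoeon	coi5p_698	698	BsaBI	698
gelotopoeon	coi5p_698	698	BsaI	698
punctigera	coi3p_511	511	Bco5I	511
punctigera	coi3p_511	511	AquVI	511
punctigera	coi3p_511	511	BseRI	468,43
punctigera	coi3p_511	511	Eco130I	511
armigera	coi3p_511	511	Bco5I	511
armigera	coi3p_511	511	AquVI	511
armigera	coi3p_511	511	BseRI	511
armigera	coi3p_511	511	Eco130I	511
assulta	coi3p_511	511	Bco5I	511
assulta	coi3p_511	511	AquVI	267,244
assulta	coi3p_511	511	BseRI	511
assulta	coi3p_511	511	Eco130I	511
zea	coi3p_511	511	Bco5I	96,415
zea	coi3p_511	511	AquVI	511
zea	coi3p_511	511	BseRI	511
zea	coi3p_511	511	Eco130I	511
gelotopoeon	coi3p_511	511	Bco5I	511
gelotopoeon	coi3p_511	511	AquVI	458,53
gelotopoeon	coi3p_511	511	BseRI	511
gelotopoeon	coi3p_511	511	Eco130I	300,211
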