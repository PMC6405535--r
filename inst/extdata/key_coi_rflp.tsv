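# Consolidated five-species Helicoverpa COI PCR-RFLP diagnostic key.
# Regions: coi5p_698 = 698 bp 5' COI amplicon; coi3p_511 = 511 bp 3' COI
# amplicon. Uncut cells are encoded as the single full-length fragment.
#
# The published table's 698 bp column-to-enzyme mapping is typographically
# garbled. This packaged mapping places the two identical assulta cut
# patterns under the isoschizomer pair BseJI/BsaBI and zea's 584+114 pattern
# under BsaI -- the only reading in which every row is simultaneously
# satisfiable by a real sequence (an isoschizomer cannot cut for one species
# while its twin does not). The alternate reading ships as
# key_coi_rflp_altmap.tsv.
#
# armigera and gelotopoeon are both uncut across the 698 bp panel and are
# not separable on that region; use coi3p_511 for New World samples.
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
assulta	coi5p_698	698	BsaBI	461,237
assulta	coi5p_698	698	BsaI	698
zea	coi5p_698	698	BseJI	698
zea	coi5p_698	698	BpuEI	698
zea	coi5p_698	698	BsaBI	698
zea	coi5p_698	698	BsaI	584,114
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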