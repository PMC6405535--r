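# Diagnostic amplicon regions: name<TAB>expected length (bp)<TAB>reference
# amplicon FASTA (path relative to this file; one reference per species,
# record ids <species>_<region>). The packaged references are synthetic
# fixtures generated by make_amplicon() with pinned seeds.
coi5p_698	698	synthetic_ref_amplicons.fa
coi3p_511	511	synthetic_ref_amplicons.fa
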