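id	lineage
TS0001	Phylum01;Class01;Order001;Family001;Genus0001;Genus0001 species1
TS0002	Phylum02;Class02;Order001;Family001;Genus0002;Genus0002 species2
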