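source_rank	source_name	target_rank	target_name	note
genus	Escherichia/Shigella	genus	Escherichia	RDP combines these genera; Escherichia reference is the closer proteome
genus	Clostridium sensu stricto	genus	Clostridium	RDP subdivision of Clostridium; map to the NCBI genus
genus	Clostridium XlVa	genus	Lachnoclostridium	RDP cluster XIVa corresponds to Lachnoclostridium in NCBI
phylum	Cyanobacteria/Chloroplast	phylum	Cyanobacteria	RDP merges the chloroplast lineage into this phylum label
genus	GpI	genus	Nostoc	RDP cyanobacterial group I; nearest NCBI genus-level reference
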