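tryptophan_metab	Tryptophan and indole metabolism (synthetic set)	Kynurenine	Serotonin	3-Indolepropionic acid
trimethylated	Trimethylated osmolytes and carnitine shuttle (synthetic set)	TMAO	5-AVAB	Carnitine
polyphenol_microbial	Microbial polyphenol degradation products (synthetic set)	Hippuric acid	Catechol-O-sulfate
lysine_degradation	Lysine degradation (synthetic set)	Pipecolic acid	Carnitine
alkaloid	Dietary glycoalkaloid metabolism (synthetic set)	Solanidine
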