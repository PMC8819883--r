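compound_id	monoisotopic_mass
TMAO	75.0684
5-AVAB	159.1259
Hippuric acid	179.0582
Pipecolic acid	129.0790
Kynurenine	208.0848
3-Indolepropionic acid	189.0790
Serotonin	176.0950
Catechol-O-sulfate	189.9936
Carnitine	161.1052
Solanidine	397.3345
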