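dataset,go_guided_moc,semi_feaclustmoo,mo_fuzzy,moga,som,avg_linkage
arabidopsis,0.49,0.46,0.41,0.40,0.23,0.32
cell_cycle,0.63,0.50,0.43,0.42,0.38,0.44
sporulation,0.80,0.70,0.59,0.58,0.58,0.50
serum,0.58,0.44,0.40,0.38,0.34,0.36
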