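id	dGf0	citation
H2O	-237.17	compilation (anaerobe bioenergetics tables)
HCO3	-586.85	compilation (anaerobe bioenergetics tables)
CH4	-50.75	compilation (anaerobe bioenergetics tables)
H2	0	compilation (anaerobe bioenergetics tables)
acetate	-369.41	compilation (anaerobe bioenergetics tables)
H	-39.87	pH 7 transformed proton term
Fe2	-78.87	compilation (anaerobe bioenergetics tables)
FeOH3	-693.44	derived from the Fe(OH)3/Fe2+ couple via the printed H2 oxidation dG0'
oleate	-174.63	derived from the printed beta-oxidation dG0'
e	0	formal electron (reference)
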