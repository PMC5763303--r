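format-version: 1.2
! Synthetic toy taxonomy slice: the three animal drug sources (tiger,
! snake, silkworm) under their shared branch points. TOYTAX ids are
! package-local stand-ins for NCBITaxon ids.

[Term]
id: TOYTAX:0000001
name: Eukaryota

[Term]
id: TOYTAX:0000002
name: Bilateria
is_a: TOYTAX:0000001

[Term]
id: TOYTAX:0000003
name: Amniota
is_a: TOYTAX:0000002

[Term]
id: TOYTAX:0000004
name: Insecta
is_a: TOYTAX:0000002

[Term]
id: TOYTAX:0000005
name: Panthera tigris
synonym: "tiger" EXACT []
is_a: TOYTAX:0000003

[Term]
id: TOYTAX:0000006
name: Ptyas dhumnades
synonym: "black-tail snake" EXACT []
is_a: TOYTAX:0000003

[Term]
id: TOYTAX:0000007
name: Bombyx mori
synonym: "silkworm" EXACT []
is_a: TOYTAX:0000004
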