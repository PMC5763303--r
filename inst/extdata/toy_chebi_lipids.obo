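format-version: 1.2
! Hand-built ChEBI slice around the terpenoid branches relevant to
! anti-rheumatism drug ingredients, with two application-role terms and
! one asserted has_role link (triptolide -> anti-inflammatory agent).

[Term]
id: CHEBI:24431
name: chemical entity

[Term]
id: CHEBI:26873
name: terpenoid
is_a: CHEBI:24431

[Term]
id: CHEBI:23849
name: diterpenoid
is_a: CHEBI:26873

[Term]
id: CHEBI:36615
name: triterpenoid
is_a: CHEBI:26873

[Term]
id: CHEBI:25872
name: pentacyclic triterpenoid
is_a: CHEBI:36615

[Term]
id: CHEBI:9747
name: triptolide
is_a: CHEBI:23849
relationship: has_role CHEBI:67079

[Term]
id: CHEBI:9740
name: tripdiolide
is_a: CHEBI:23849

[Term]
id: CHEBI:63959
name: celastrol
is_a: CHEBI:25872

[Term]
id: CHEBI:50906
name: role

[Term]
id: CHEBI:67079
name: anti-inflammatory agent
is_a: CHEBI:50906

[Term]
id: CHEBI:35610
name: antineoplastic agent
is_a: CHEBI:50906
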