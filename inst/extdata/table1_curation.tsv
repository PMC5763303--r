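# Transcription of the published ingredient table: 42 chemical entries
# (anti-inflammatory / antineoplastic / dual-role sections) with their
# drugs as printed, including the printed label variants 'Mulberry Ttwig'
# and 'Trypterygii Hypoglauci Radix'. Source-fact organism ids are
# SYNTHETIC placeholders (NCBITaxon:9000001..) - the supplement with the
# real taxon ids is not packaged; anatomy ids are approximate PO/UBERON
# terms for the anatomic part named in each drug label.
drug	category	fact_type	organism_id	anatomy_id	chemical_label	chemical_id	roles	ae_label	ae_id
Acanthopanax Root Bark	TCM dispelling pathogenic wind and dampness drug	source	NCBITaxon:9000001	PO:0009005					
Chinese Clematis Root	TCM dispelling pathogenic wind and dampness drug	source	NCBITaxon:9000002	PO:0009005					
Chinese Starjasmine Stem	TCM dispelling pathogenic wind and dampness drug	source	NCBITaxon:9000003	PO:0009047					
Chinese Taxillus Herb	TCM dispelling pathogenic wind and dampness drug	source	NCBITaxon:9000004	PO:0000003					
Common Floweringqince Fruit	TCM dispelling pathogenic wind and dampness drug	source	NCBITaxon:9000005	PO:0009001					
Common Threewingnut Root	TCM winddamp-dispelling and heat-clearing drug	source	NCBITaxon:9000006	PO:0009005					
Debark Peony Root	TCM supplementing and boosting drug	source	NCBITaxon:9000007	PO:0009005					
Doubleteeth Pubescent Angelica Root	TCM dispelling pathogenic wind and dampness drug	source	NCBITaxon:9000008	PO:0009005					
Fourstamen Stephania Root	TCM dispelling pathogenic wind and dampness drug	source	NCBITaxon:9000009	PO:0009005					
Harlequin Glorybower Leaf	TCM dispelling pathogenic wind and dampness drug	source	NCBITaxon:9000010	PO:0025034					
Largeleaf Gentian Root	TCM dispelling pathogenic wind and dampness drug	source	NCBITaxon:9000011	PO:0009005					
Mulberry Ttwig	TCM dispelling pathogenic wind and dampness drug	source	NCBITaxon:9000012	PO:0009047					
Mulberry Twig	TCM dispelling pathogenic wind and dampness drug	source	NCBITaxon:9000013	PO:0009047					
Nux Vomica	TCM promoting blood circulation and removing blood stasis drug	source	NCBITaxon:9000014	PO:0009010					
Silk-worm Droppings	TCM dispelling pathogenic wind and dampness drug	source	NCBITaxon:9000015	UBERON:0001988					
Tiger Bone	TCM dispelling pathogenic wind and dampness drug	source	NCBITaxon:9000016	UBERON:0001474					
Tripterygii Hypoglauci Radix	TCM wind-damp dispelling and cold-dispersing drug	source	NCBITaxon:9000017	PO:0009005					
Trypterygii Hypoglauci Radix	TCM wind-damp dispelling and cold-dispersing drug	source	NCBITaxon:9000018	PO:0009005					
Wooly Datchmanspipe Herb	TCM dispelling pathogenic wind and dampness drug	source	NCBITaxon:9000019	PO:0000003					
Common Floweringqince Fruit		chemical			4-terpineol	CHEBI_78884	anti-inflammatory;antineoplastic		
Silk-worm Droppings;Tiger Bone		chemical			all-trans-retinoic acid	CHEBI_15367	anti-inflammatory;antineoplastic		
Chinese Clematis Root;Common Floweringqince Fruit		chemical			botulin	CHEBI_3086	anti-inflammatory;antineoplastic		
Chinese Taxillus Herb;Common Floweringqince Fruit;Debark Peony Root		chemical			betulinic acid	CHEBI_3087	anti-inflammatory;antineoplastic		
Common Threewingnut Root;Tripterygii Hypoglauci Radix		chemical			celastrol	CHEBI_63959	anti-inflammatory;antineoplastic		
Nux Vomica		chemical			ethyl trans-caffeate	CHEBI_132714	anti-inflammatory;antineoplastic		
Fourstamen Stephania Root		chemical			fangchinoline	CHEBI_132893	anti-inflammatory;antineoplastic		
Common Threewingnut Root		chemical			tripdiolide	CHEBI_9740	anti-inflammatory;antineoplastic		
Common Threewingnut Root;Tripterygii Hypoglauci Radix		chemical			triptolide	CHEBI_9747	anti-inflammatory;antineoplastic		
Acanthopanax Root Bark		chemical			(+)-sesamin	CHEBI_66470	antineoplastic		
Common Threewingnut Root		chemical			(+)-syringaresinol	CHEBI_47	antineoplastic		
Acanthopanax Root Bark;Chinese Taxillus Herb;Common Floweringqince Fruit;Nux Vomica		chemical			3,4-dihydroxybenzoic acid	CHEBI_36062	antineoplastic		
Chinese Starjasmine Stem;Harlequin Glorybower Leaf		chemical			apigenin	CHEBI_18388	antineoplastic		
Wooly Datchmanspipe Herb		chemical			beta-elemene	CHEBI_62854	antineoplastic		
Chinese Clematis Root		chemical			daidzein	CHEBI_28197	antineoplastic		
Common Threewingnut Root		chemical			emodin	CHEBI_42223	antineoplastic		
Common Floweringqince Fruit;Nux Vomica		chemical			gallic acid	CHEBI_30778	antineoplastic		
Chinese Clematis Root		chemical			genistein	CHEBI_28088	antineoplastic		
Chinese Clematis Root		chemical			hesperetin	CHEBI_28230	antineoplastic		
Harlequin Glorybower Leaf		chemical			hydroxytyrosol	CHEBI_68889	antineoplastic		
Largeleaf Gentian Root		chemical			isoorientin	CHEBI_17965	antineoplastic		
Common Floweringqince Fruit;Chinese Starjasmine Stem		chemical			luteolin	CHEBI_15864	antineoplastic		
Common Floweringqince Fruit		chemical			maslinic acid	CHEBI_66682	antineoplastic		
Doubleteeth Pubescent Angelica Root		chemical			methoxsalen	CHEBI_18358	antineoplastic		
Mulberry Twig		chemical			morin	CHEBI_75092	antineoplastic		
Mulberry Ttwig		chemical			morusin	CHEBI_7005	antineoplastic		
Chinese Starjasmine Stem		chemical			naringin	CHEBI_28819	antineoplastic		
Chinese Clematis Root		chemical			neohesperidin	CHEBI_59016	antineoplastic		
Chinese Clematis Root;Common Threewingnut Root		chemical			nobiletin	CHEBI_7602	antineoplastic		
Tripterygii Hypoglauci Radix		chemical			procyanidin B4	CHEBI_27589	antineoplastic		
Chinese Clematis Root;Common Floweringqince Fruit;Chinese Taxillus Herb		chemical			quercetin	CHEBI_16243	antineoplastic		
Common Threewingnut Root		chemical			sciscllascilloside E-1	CHEBI_66439	antineoplastic		
Common Threewingnut Root		chemical			triptonide	CHEBI_132267	antineoplastic		
Harlequin Glorybower Leaf		chemical			acteoside	CHEBI_132853	anti-inflammatory		
Common Floweringqince Fruit		chemical			decanoic acid	CHEBI_30813	anti-inflammatory		
Chinese Taxillus Herb;Nux Vomica		chemical			ferulic acid	CHEBI_17620	anti-inflammatory		
Chinese Taxillus Herb;Nux Vomica;Silk-worm Droppings		chemical			lupeol	CHEBI_6570	anti-inflammatory		
Common Floweringqince Fruit		chemical			maslinic acid	CHEBI_66682	anti-inflammatory		
Trypterygii Hypoglauci Radix		chemical			procyanidin B3	CHEBI_75630	anti-inflammatory		
Chinese Clematis Root		chemical			tectorigenin	CHEBI_9429	anti-inflammatory		
Common Threewingnut Root		chemical			triptonide	CHEBI_132267	anti-inflammatory		
Tripterygii Hypoglauci Radix		chemical			fredelin	CHEBI_5171	anti-inflammatory		
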