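taxon	tribe	subtribe	region	is_outgroup	is_root
Uloma_mexicana	Ulomini	unassigned	Mexico, Central America	TRUE	TRUE
Helops_punctipennis	Helopini	Helopina	U.S.A.	FALSE	FALSE
Entomogonus_peyronis	Helopini	Helopina	Asia	FALSE	FALSE
Raiboscelis_corvinus	Helopini	Helopina	Asia, Europe	FALSE	FALSE
Probaticus_tentyrioides	Helopini	Helopina	Asia, Europe	FALSE	FALSE
Helops_rossii	Helopini	Helopina	Europe	FALSE	FALSE
Helops_insignis	Helopini	Helopina	North of Africa	FALSE	FALSE
Helops_cisteloides	Helopini	Helopina	U.S.A.	FALSE	FALSE
Nautes_enoplopoides	Helopini	unassigned	Guatemala	FALSE	FALSE
Helops_perforatus	Helopini	Helopina	Mexico, U.S.A.	FALSE	FALSE
Nautes_striatipennis	Helopini	unassigned	Mexico	FALSE	FALSE
Helops_farctus	Helopini	Helopina	U.S.A.	FALSE	FALSE
Nautes_splendens	Helopini	unassigned	Panama	FALSE	FALSE
Tarpela_browni	Helopini	Helopina	Nicaragua	FALSE	FALSE
Tarpela_torrida	Helopini	Helopina	Mexico	FALSE	FALSE
Nautes_magnificus	Helopini	unassigned	Guatemala	FALSE	FALSE
Tarpela_depressa	Helopini	Helopina	Mexico	FALSE	FALSE
Nautes_varians	Helopini	unassigned	Mexico	FALSE	FALSE
Tarpela_contigua	Helopini	Helopina	Mexico	FALSE	FALSE
Nautes_belti	Helopini	unassigned	Central America	FALSE	FALSE
Nautes_fervidus	Helopini	unassigned	Mexico, Central America	FALSE	FALSE
Tarpela_aerifera	Helopini	Helopina	Mexico, Central America	FALSE	FALSE
Tarpela_reticulata	Helopini	Helopina	Honduras	FALSE	FALSE
Helops_rufipes	Helopini	Helopina	Mexico, U.S.A.	FALSE	FALSE
Helops_inanis	Helopini	Helopina	Mexico	FALSE	FALSE
Tarpela_costata	Helopini	Helopina	Mexico, Nicaragua	FALSE	FALSE
Nalassus_plebejus	Helopini	Cylindrinotina	Europe, Asia	FALSE	FALSE
Helops_aereus	Helopini	Helopina	U.S.A.	FALSE	FALSE
Odocnemis_californicus	Helopini	Cylindrinotina	Mexico, U.S.A.	FALSE	FALSE
Stenomax_aeneus	Helopini	Cylindrinotina	Europe	FALSE	FALSE
Tarpela_cordicollis	Helopini	Helopina	Japan	FALSE	FALSE
Hypogena_biimpressa	Ulomini	unassigned	Mexico, Central America, South America	TRUE	FALSE
Tenebrio_molitor	Tenebrionini	unassigned	global	TRUE	FALSE
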