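specimen_id	species	genus	family	site_id	method	sequence_id
SIM0001	Genus01 species001	Genus01	Famidae01	site01	pan_trap	SEQ0001
SIM0002	Genus01 species001	Genus01	Famidae01	site05	pan_trap	SEQ0002
SIM0003	Genus01 species001	Genus01	Famidae01	site02	pan_trap	SEQ0003
SIM0004	Genus01 species002	Genus01	Famidae01	site04	pan_trap	SEQ0004
SIM0005	Genus01 species002	Genus01	Famidae01	site05	pan_trap	SEQ0005
SIM0006	Genus01 species002	Genus01	Famidae01	site05	net	SEQ0006
SIM0007	Genus02 species003	Genus02	Famidae01	site05	pan_trap	SEQ0007
SIM0008	Genus02 species003	Genus02	Famidae01	site02	pan_trap	SEQ0008
SIM0009	Genus02 species003	Genus02	Famidae01	site02	pan_trap	SEQ0009
SIM0010	Genus02 species004	Genus02	Famidae01	site05	pan_trap	SEQ0010
SIM0011	Genus02 species004	Genus02	Famidae01	site03	pan_trap	SEQ0011
SIM0012	Genus02 species004	Genus02	Famidae01	site02	pan_trap	SEQ0012
SIM0013	Genus03 species005	Genus03	Famidae02	site02	pan_trap	SEQ0013
SIM0014	Genus03 species005	Genus03	Famidae02	site01	pan_trap	SEQ0014
SIM0015	Genus03 species005	Genus03	Famidae02	site05	pan_trap	SEQ0015
SIM0016	Genus03 species006	Genus03	Famidae02	site04	pan_trap	SEQ0016
SIM0017	Genus03 species006	Genus03	Famidae02	site03	pan_trap	SEQ0017
SIM0018	Genus03 species006	Genus03	Famidae02	site04	pan_trap	SEQ0018
SIM0019	Genus04 species007	Genus04	Famidae02	site01	pan_trap	SEQ0019
SIM0020	Genus04 species007	Genus04	Famidae02	site05	pan_trap	SEQ0020
SIM0021	Genus04 species007	Genus04	Famidae02	site03	pan_trap	SEQ0021
SIM0022	Genus04 species008	Genus04	Famidae02	site03	pan_trap	SEQ0022
SIM0023	Genus04 species008	Genus04	Famidae02	site05	pan_trap	SEQ0023
SIM0024	Genus04 species008	Genus04	Famidae02	site04	pan_trap	SEQ0024
SIM0025		Genus03	Famidae02	site01	pan_trap	SEQ0025
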