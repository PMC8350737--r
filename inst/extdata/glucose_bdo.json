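{"reactions":[{"id":"glf","equation":"1 glc_ext -> 1 glc","dg0_prime_kj_mol":0,"reversible":false,"rel_flux":1,"kcat_s":null,"km":null,"mw_g_mol":null},{"id":"glk","equation":"1 glc + 1 atp -> 1 g6p + 1 adp","dg0_prime_kj_mol":"NA","reversible":true,"rel_flux":1,"kcat_s":null,"km":null,"mw_g_mol":null},{"id":"g6pdh","equation":"1 g6p + 1 nadp -> 1 pgl6 + 1 nadph","dg0_prime_kj_mol":"NA","reversible":true,"rel_flux":1,"kcat_s":null,"km":null,"mw_g_mol":null},{"id":"pgl","equation":"1 pgl6 -> 1 pg6","dg0_prime_kj_mol":"NA","reversible":true,"rel_flux":1,"kcat_s":null,"km":null,"mw_g_mol":null},{"id":"edd","equation":"1 pg6 -> 1 kdpg","dg0_prime_kj_mol":"NA","reversible":true,"rel_flux":1,"kcat_s":null,"km":null,"mw_g_mol":null},{"id":"eda","equation":"1 kdpg -> 1 pyr + 1 g3p","dg0_prime_kj_mol":"NA","reversible":true,"rel_flux":1,"kcat_s":null,"km":null,"mw_g_mol":null},{"id":"gapdh","equation":"1 g3p + 1 nad + 1 pi -> 1 dpg13 + 1 nadh","dg0_prime_kj_mol":"NA","reversible":true,"rel_flux":1,"kcat_s":null,"km":null,"mw_g_mol":null},{"id":"pgk","equation":"1 dpg13 + 1 adp -> 1 pg3 + 1 atp","dg0_prime_kj_mol":"NA","reversible":true,"rel_flux":1,"kcat_s":null,"km":null,"mw_g_mol":null},{"id":"pgm","equation":"1 pg3 -> 1 pg2","dg0_prime_kj_mol":"NA","reversible":true,"rel_flux":1,"kcat_s":null,"km":null,"mw_g_mol":null},{"id":"eno","equation":"1 pg2 -> 1 pep","dg0_prime_kj_mol":"NA","reversible":true,"rel_flux":1,"kcat_s":null,"km":null,"mw_g_mol":null},{"id":"pyk","equation":"1 pep + 1 adp -> 1 pyr + 1 atp","dg0_prime_kj_mol":"NA","reversible":true,"rel_flux":1,"kcat_s":null,"km":null,"mw_g_mol":null},{"id":"als","equation":"2 pyr -> 1 alac + 1 co2","dg0_prime_kj_mol":"NA","reversible":false,"rel_flux":1,"kcat_s":null,"km":null,"mw_g_mol":null},{"id":"aldc","equation":"1 alac -> 1 actn + 1 co2","dg0_prime_kj_mol":"NA","reversible":false,"rel_flux":1,"kcat_s":null,"km":null,"mw_g_mol":null},{"id":"bdh","equation":"1 actn + 1 nadh -> 1 bdo + 1 nad","dg0_prime_kj_mol":"NA","reversible":true,"rel_flux":1,"kcat_s":null,"km":null,"mw_g_mol":null}],"fixed_conc_mM":{"glc_ext":443},"conc_lb_mM":0.001,"conc_ub_mM":10,"boundary":["glc_ext","xyl_ext","bdo","co2","atp","adp","nad","nadh","nadp","nadph","pi"],"temperature_K":298.15}
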