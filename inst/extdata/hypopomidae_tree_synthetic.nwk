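(Gymnotus_carapo,(Sternopygus_macrurus,((Rhamphichthys_rostratus,Gymnorhamphichthys_rondoni)Rhamphichthyidae,((Steatogenys_elegans,Steatogenys_duidae)Steatogenys,((Brachyhypopomus_brevirostris,Brachyhypopomus_hendersoni)T,((Brachyhypopomus_regani,Brachyhypopomus_batesi)M,((Brachyhypopomus_bennetti,Brachyhypopomus_walteri)K,(Brachyhypopomus_flavipomus,((Brachyhypopomus_gauderio,Brachyhypopomus_pinnicaudatus)J,(Brachyhypopomus_hamiltoni,Brachyhypopomus_beebei)H)2)C)B)A)Brachyhypopomus)Hypopomidae)Rhamphichthyoidea)Outgroups)Root;
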