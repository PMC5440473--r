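reaction_id,name,category,species,coefficient,limiting_source
MG,Hydrogenotrophic methanogenesis,methanogenesis,CO2(aq),-1,dic_uM
MG,Hydrogenotrophic methanogenesis,methanogenesis,H2(aq),-4,h2_uM
MG,Hydrogenotrophic methanogenesis,methanogenesis,CH4(aq),1,
MG,Hydrogenotrophic methanogenesis,methanogenesis,H2O,2,
AM,Acetoclastic methanogenesis,methanogenesis,acetate-,-1,acetate_scenario
AM,Acetoclastic methanogenesis,methanogenesis,H2O,-1,
AM,Acetoclastic methanogenesis,methanogenesis,CH4(aq),1,
AM,Acetoclastic methanogenesis,methanogenesis,HCO3-,1,
AOM_SO4,AOM coupled to sulfate reduction,anaerobic_methanotrophy,CH4(aq),-1,ch4_uM
AOM_SO4,AOM coupled to sulfate reduction,anaerobic_methanotrophy,SO4-2,-1,so4_scenario
AOM_SO4,AOM coupled to sulfate reduction,anaerobic_methanotrophy,HCO3-,1,
AOM_SO4,AOM coupled to sulfate reduction,anaerobic_methanotrophy,HS-,1,
AOM_SO4,AOM coupled to sulfate reduction,anaerobic_methanotrophy,H2O,1,
AOM_NO3,AOM coupled to nitrate reduction,anaerobic_methanotrophy,CH4(aq),-1,ch4_uM
AOM_NO3,AOM coupled to nitrate reduction,anaerobic_methanotrophy,NO3-,-4,no3_from_nox
AOM_NO3,AOM coupled to nitrate reduction,anaerobic_methanotrophy,HCO3-,1,
AOM_NO3,AOM coupled to nitrate reduction,anaerobic_methanotrophy,NO2-,4,
AOM_NO3,AOM coupled to nitrate reduction,anaerobic_methanotrophy,H+,1,
AOM_NO3,AOM coupled to nitrate reduction,anaerobic_methanotrophy,H2O,1,
AeMO,Aerobic methane oxidation,aerobic_methanotrophy,CH4(aq),-1,ch4_uM
AeMO,Aerobic methane oxidation,aerobic_methanotrophy,O2(aq),-2,o2_scenario
AeMO,Aerobic methane oxidation,aerobic_methanotrophy,HCO3-,1,
AeMO,Aerobic methane oxidation,aerobic_methanotrophy,H+,1,
AeMO,Aerobic methane oxidation,aerobic_methanotrophy,H2O,1,
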