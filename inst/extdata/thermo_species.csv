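species,formula,charge,dGf_25C_kJ_mol,dHf_25C_kJ_mol,phase,source
H2O,H2O,0,-237.18,-285.83,liquid,CODATA / SUPCRT-consistent (-56.688 / -68.317 kcal)
H+,H,1,0,0,aqueous,convention (zero by definition)
OH-,HO,-1,-157.30,-230.02,aqueous,Shock & Helgeson 1988 (-37.595 / -54.977 kcal)
CO2(aq),CO2,0,-385.97,-413.80,aqueous,Shock & Helgeson 1988 (-92.25 / -98.90 kcal)
HCO3-,HCO3,-1,-586.94,-689.93,aqueous,Shock & Helgeson 1988 (-140.282 / -164.898 kcal)
CO3-2,CO3,-2,-527.98,-675.23,aqueous,Shock & Helgeson 1988 (-126.191 / -161.385 kcal)
CH4(aq),CH4,0,-34.45,-87.91,aqueous,Shock & Helgeson 1990 (-8.234 / -21.01 kcal)
H2(aq),H2,0,17.72,-4.18,aqueous,Shock & Helgeson 1990 (4.236 / -1.0 kcal)
O2(aq),O2,0,16.54,-12.13,aqueous,Shock & Helgeson 1990 (3.954 / -2.9 kcal)
acetate-,C2H3O2,-1,-369.32,-486.01,aqueous,Shock & Helgeson 1990 (-88.27 / -116.16 kcal)
acetic_acid(aq),C2H4O2,0,-396.48,-485.76,aqueous,Shock & Helgeson 1990 (-94.76 / -116.10 kcal)
SO4-2,SO4,-2,-744.46,-909.60,aqueous,Shock & Helgeson 1988 (-177.93 / -217.40 kcal)
HS-,HS,-1,11.97,-16.11,aqueous,Shock & Helgeson 1988 (2.860 / -3.85 kcal)
NO3-,NO3,-1,-110.91,-206.81,aqueous,Shock & Helgeson 1988 (-26.507 / -49.429 kcal)
NO2-,NO2,-1,-32.22,-104.60,aqueous,Shock & Helgeson 1988 (-7.70 / -25.0 kcal)
NH4+,NH4,1,-79.45,-133.26,aqueous,Shock & Helgeson 1988 (-18.99 / -31.85 kcal)
NH3(aq),NH3,0,-26.57,-80.29,aqueous,Shock & Helgeson 1988 (-6.35 / -19.19 kcal)
H2PO4-,H2PO4,-1,-1130.27,-1296.29,aqueous,Shock & Helgeson 1988 (-270.14 / -309.82 kcal)
HPO4-2,HPO4,-2,-1089.14,-1292.08,aqueous,Shock & Helgeson 1988 (-260.31 / -308.815 kcal)
PO4-3,PO4,-3,-1018.80,-1277.38,aqueous,Shock & Helgeson 1988 (-243.50 / -305.30 kcal)
Na+,Na,1,-261.88,-240.28,aqueous,Shock & Helgeson 1988 (-62.591 / -57.433 kcal)
Cl-,Cl,-1,-131.29,-167.08,aqueous,Shock & Helgeson 1988 (-31.379 / -39.933 kcal)
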