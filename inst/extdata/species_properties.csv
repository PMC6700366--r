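species,has_hydration,D_water_m2_h,molar_mass_g_mol,henry_mol_L_bar,mgL_reference_form
water,FALSE,NA,18.015,NA,H2O
proton,FALSE,NA,1.008,NA,H+
hydroxide,FALSE,NA,17.007,NA,OH-
oxygen,FALSE,7.56e-06,31.998,0.00126,O2
ammonia,FALSE,6.84e-06,17.031,NA,NH3
carbonate,TRUE,6.91e-06,44.009,0.0339,CO2
nitrite,FALSE,6.12e-06,46.005,NA,NO2-
nitrate,FALSE,6.12e-06,62.004,NA,NO3-
glucose,FALSE,2.41e-06,180.156,NA,C6H12O6
acetate,FALSE,3.96e-06,59.044,NA,CH3COO-
hydrogen,FALSE,1.62e-05,2.016,0.00078,H2
methane,FALSE,5.4e-06,16.043,0.0014,CH4
phosphate,FALSE,2.74e-06,97.995,NA,H3PO4
biomass,FALSE,NA,24.626,NA,Biomass
sodium,FALSE,4.79e-06,22.99,NA,Na+
chloride,FALSE,7.31e-06,35.453,NA,Cl-
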