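species,form,charge,dG_f_kJ_mol,dG_f_standard_kJ_mol,n_C,n_H,n_N,n_O,n_P,source
water,H2O,0,-237.18,-237.18,0,2,0,1,0,standard (Thauer 1977 compilation)
proton,H+,1,0,0,0,1,0,0,0,standard (Thauer 1977 compilation)
hydroxide,OH-,-1,-157.29,-157.29,0,1,0,1,0,standard (Thauer 1977 compilation)
oxygen,O2,0,16.4,16.4,0,0,0,2,0,standard (Thauer 1977 compilation)
ammonia,NH4+,1,-79.37,-79.37,0,4,1,0,0,standard (Thauer 1977 compilation)
ammonia,NH3,0,-26.57,-26.57,0,3,1,0,0,standard (Thauer 1977 compilation)
carbonate,CO2,0,-385.913844,-385.913843615095,1,0,0,2,0,standard (Thauer 1977 compilation)
carbonate,HCO3-,-1,-586.85,-586.85,1,1,0,3,0,standard (Thauer 1977 compilation)
carbonate,CO3-2,-2,-527.889543,-527.889542591508,1,0,0,3,0,standard (Thauer 1977 compilation)
nitrite,HNO2,0,-303.042919,-50.769998700639,0,1,1,2,0,calibrated to published yield set
nitrite,NO2-,-1,-284.492921,-32.22,0,0,1,2,0,calibrated to published yield set
nitrate,HNO3,0,-534.394179,-103.920000519744,0,1,1,3,0,calibrated to published yield set
nitrate,NO3-,-1,-541.814179,-111.34,0,0,1,3,0,calibrated to published yield set
glucose,C6H12O6,0,-866.564001,-917.22,6,12,0,6,0,calibrated to published yield set
acetate,CH3COOH,0,-396.578613,-396.578613481551,2,4,0,2,0,standard (Thauer 1977 compilation)
acetate,CH3COO-,-1,-369.41,-369.41,2,3,0,2,0,standard (Thauer 1977 compilation)
hydrogen,H2,0,31.50376,17.57,0,2,0,0,0,calibrated to published yield set
methane,CH4,0,-53.469141,-34.33,1,4,0,0,0,calibrated to published yield set
phosphate,H3PO4,0,-1142.6,-1142.6,0,3,0,4,1,standard (Thauer 1977 compilation)
phosphate,H2PO4-,-1,-1130.328462,-1130.32846239804,0,2,0,4,1,standard (Thauer 1977 compilation)
phosphate,HPO4-2,-2,-1089.233081,-1089.23308066124,0,1,0,4,1,standard (Thauer 1977 compilation)
phosphate,PO4-3,-3,-1018.743086,-1018.74308559881,0,0,0,4,1,standard (Thauer 1977 compilation)
biomass,Biomass,0,-67,-67,1,1.8,0.2,0.5,0,standard (Thauer 1977 compilation)
sodium,Na+,1,-261.88,-261.88,0,0,0,0,0,standard (Thauer 1977 compilation)
chloride,Cl-,-1,-131.26,-131.26,0,0,0,0,0,standard (Thauer 1977 compilation)
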