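strategy,state,year,value,provenance
CAPD,CAPD,1,0.78000000000000003,placeholder
CAPD,CAPD,2,0.77000000000000002,placeholder
CAPD,CAPD,3,0.76000000000000001,placeholder
CAPD,CAPD_ICO,1,0.80000000000000004,placeholder
CAPD,CAPD_ICO,2,0.79000000000000004,placeholder
CAPD,CAPD_ICO,3,0.78000000000000003,placeholder
CAPD,APD,1,0.73999999999999999,placeholder
CAPD,APD,2,0.71999999999999997,placeholder
CAPD,APD,3,0.69999999999999996,placeholder
CAPD,HD,1,0.69999999999999996,placeholder
CAPD,HD,2,0.69999999999999996,placeholder
CAPD,HD,3,0.69999999999999996,placeholder
CAPD,KT,1,0.84999999999999998,placeholder
CAPD,KT,2,0.84999999999999998,placeholder
CAPD,KT,3,0.84999999999999998,placeholder
CAPD_ICO,CAPD,1,0.78000000000000003,placeholder
CAPD_ICO,CAPD,2,0.77000000000000002,placeholder
CAPD_ICO,CAPD,3,0.76000000000000001,placeholder
CAPD_ICO,CAPD_ICO,1,0.80000000000000004,placeholder
CAPD_ICO,CAPD_ICO,2,0.79000000000000004,placeholder
CAPD_ICO,CAPD_ICO,3,0.78000000000000003,placeholder
CAPD_ICO,APD,1,0.73999999999999999,placeholder
CAPD_ICO,APD,2,0.71999999999999997,placeholder
CAPD_ICO,APD,3,0.69999999999999996,placeholder
CAPD_ICO,HD,1,0.69999999999999996,placeholder
CAPD_ICO,HD,2,0.69999999999999996,placeholder
CAPD_ICO,HD,3,0.69999999999999996,placeholder
CAPD_ICO,KT,1,0.84999999999999998,placeholder
CAPD_ICO,KT,2,0.84999999999999998,placeholder
CAPD_ICO,KT,3,0.84999999999999998,placeholder
APD,CAPD,1,0.78000000000000003,placeholder
APD,CAPD,2,0.77000000000000002,placeholder
APD,CAPD,3,0.76000000000000001,placeholder
APD,CAPD_ICO,1,0.80000000000000004,placeholder
APD,CAPD_ICO,2,0.79000000000000004,placeholder
APD,CAPD_ICO,3,0.78000000000000003,placeholder
APD,APD,1,0.73999999999999999,placeholder
APD,APD,2,0.71999999999999997,placeholder
APD,APD,3,0.69999999999999996,placeholder
APD,HD,1,0.69999999999999996,placeholder
APD,HD,2,0.69999999999999996,placeholder
APD,HD,3,0.69999999999999996,placeholder
APD,KT,1,0.84999999999999998,placeholder
APD,KT,2,0.84999999999999998,placeholder
APD,KT,3,0.84999999999999998,placeholder
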