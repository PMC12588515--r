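strategy,state,year,component,value,informal_care,provenance
CAPD,CAPD,1,medical,560000,FALSE,placeholder
CAPD,CAPD,1,nonmedical,60000,TRUE,placeholder
CAPD,CAPD,2,medical,530000,FALSE,placeholder
CAPD,CAPD,2,nonmedical,60000,TRUE,placeholder
CAPD,CAPD,3,medical,510000,FALSE,placeholder
CAPD,CAPD,3,nonmedical,60000,TRUE,placeholder
CAPD,CAPD_ICO,1,medical,560000,FALSE,placeholder
CAPD,CAPD_ICO,1,icodextrin,91250,FALSE,placeholder
CAPD,CAPD_ICO,1,nonmedical,60000,TRUE,placeholder
CAPD,CAPD_ICO,2,medical,530000,FALSE,placeholder
CAPD,CAPD_ICO,2,icodextrin,91250,FALSE,placeholder
CAPD,CAPD_ICO,2,nonmedical,60000,TRUE,placeholder
CAPD,CAPD_ICO,3,medical,510000,FALSE,placeholder
CAPD,CAPD_ICO,3,icodextrin,91250,FALSE,placeholder
CAPD,CAPD_ICO,3,nonmedical,60000,TRUE,placeholder
CAPD,APD,1,medical,660000,FALSE,placeholder
CAPD,APD,1,nonmedical,60000,TRUE,placeholder
CAPD,APD,2,medical,630000,FALSE,placeholder
CAPD,APD,2,nonmedical,60000,TRUE,placeholder
CAPD,APD,3,medical,610000,FALSE,placeholder
CAPD,APD,3,nonmedical,60000,TRUE,placeholder
CAPD,HD,1,medical,700000,FALSE,placeholder
CAPD,HD,1,nonmedical,90000,TRUE,placeholder
CAPD,HD,2,medical,700000,FALSE,placeholder
CAPD,HD,2,nonmedical,90000,TRUE,placeholder
CAPD,HD,3,medical,700000,FALSE,placeholder
CAPD,HD,3,nonmedical,90000,TRUE,placeholder
CAPD,KT,1,medical,300000,FALSE,placeholder
CAPD,KT,1,nonmedical,40000,TRUE,placeholder
CAPD,KT,2,medical,250000,FALSE,placeholder
CAPD,KT,2,nonmedical,40000,TRUE,placeholder
CAPD,KT,3,medical,250000,FALSE,placeholder
CAPD,KT,3,nonmedical,40000,TRUE,placeholder
CAPD_ICO,CAPD,1,medical,560000,FALSE,placeholder
CAPD_ICO,CAPD,1,nonmedical,60000,TRUE,placeholder
CAPD_ICO,CAPD,2,medical,530000,FALSE,placeholder
CAPD_ICO,CAPD,2,nonmedical,60000,TRUE,placeholder
CAPD_ICO,CAPD,3,medical,510000,FALSE,placeholder
CAPD_ICO,CAPD,3,nonmedical,60000,TRUE,placeholder
CAPD_ICO,CAPD_ICO,1,medical,560000,FALSE,placeholder
CAPD_ICO,CAPD_ICO,1,icodextrin,91250,FALSE,placeholder
CAPD_ICO,CAPD_ICO,1,nonmedical,60000,TRUE,placeholder
CAPD_ICO,CAPD_ICO,2,medical,530000,FALSE,placeholder
CAPD_ICO,CAPD_ICO,2,icodextrin,91250,FALSE,placeholder
CAPD_ICO,CAPD_ICO,2,nonmedical,60000,TRUE,placeholder
CAPD_ICO,CAPD_ICO,3,medical,510000,FALSE,placeholder
CAPD_ICO,CAPD_ICO,3,icodextrin,91250,FALSE,placeholder
CAPD_ICO,CAPD_ICO,3,nonmedical,60000,TRUE,placeholder
CAPD_ICO,APD,1,medical,660000,FALSE,placeholder
CAPD_ICO,APD,1,nonmedical,60000,TRUE,placeholder
CAPD_ICO,APD,2,medical,630000,FALSE,placeholder
CAPD_ICO,APD,2,nonmedical,60000,TRUE,placeholder
CAPD_ICO,APD,3,medical,610000,FALSE,placeholder
CAPD_ICO,APD,3,nonmedical,60000,TRUE,placeholder
CAPD_ICO,HD,1,medical,700000,FALSE,placeholder
CAPD_ICO,HD,1,nonmedical,90000,TRUE,placeholder
CAPD_ICO,HD,2,medical,700000,FALSE,placeholder
CAPD_ICO,HD,2,nonmedical,90000,TRUE,placeholder
CAPD_ICO,HD,3,medical,700000,FALSE,placeholder
CAPD_ICO,HD,3,nonmedical,90000,TRUE,placeholder
CAPD_ICO,KT,1,medical,300000,FALSE,placeholder
CAPD_ICO,KT,1,nonmedical,40000,TRUE,placeholder
CAPD_ICO,KT,2,medical,250000,FALSE,placeholder
CAPD_ICO,KT,2,nonmedical,40000,TRUE,placeholder
CAPD_ICO,KT,3,medical,250000,FALSE,placeholder
CAPD_ICO,KT,3,nonmedical,40000,TRUE,placeholder
APD,CAPD,1,medical,560000,FALSE,placeholder
APD,CAPD,1,nonmedical,60000,TRUE,placeholder
APD,CAPD,2,medical,530000,FALSE,placeholder
APD,CAPD,2,nonmedical,60000,TRUE,placeholder
APD,CAPD,3,medical,510000,FALSE,placeholder
APD,CAPD,3,nonmedical,60000,TRUE,placeholder
APD,CAPD_ICO,1,medical,560000,FALSE,placeholder
APD,CAPD_ICO,1,icodextrin,91250,FALSE,placeholder
APD,CAPD_ICO,1,nonmedical,60000,TRUE,placeholder
APD,CAPD_ICO,2,medical,530000,FALSE,placeholder
APD,CAPD_ICO,2,icodextrin,91250,FALSE,placeholder
APD,CAPD_ICO,2,nonmedical,60000,TRUE,placeholder
APD,CAPD_ICO,3,medical,510000,FALSE,placeholder
APD,CAPD_ICO,3,icodextrin,91250,FALSE,placeholder
APD,CAPD_ICO,3,nonmedical,60000,TRUE,placeholder
APD,APD,1,medical,660000,FALSE,placeholder
APD,APD,1,nonmedical,60000,TRUE,placeholder
APD,APD,2,medical,630000,FALSE,placeholder
APD,APD,2,nonmedical,60000,TRUE,placeholder
APD,APD,3,medical,610000,FALSE,placeholder
APD,APD,3,nonmedical,60000,TRUE,placeholder
APD,HD,1,medical,700000,FALSE,placeholder
APD,HD,1,nonmedical,90000,TRUE,placeholder
APD,HD,2,medical,700000,FALSE,placeholder
APD,HD,2,nonmedical,90000,TRUE,placeholder
APD,HD,3,medical,700000,FALSE,placeholder
APD,HD,3,nonmedical,90000,TRUE,placeholder
APD,KT,1,medical,300000,FALSE,placeholder
APD,KT,1,nonmedical,40000,TRUE,placeholder
APD,KT,2,medical,250000,FALSE,placeholder
APD,KT,2,nonmedical,40000,TRUE,placeholder
APD,KT,3,medical,250000,FALSE,placeholder
APD,KT,3,nonmedical,40000,TRUE,placeholder
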