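label,population,mean_age,sector,mean,sd,n,ci_lo,ci_hi,se,eye,device,healthy
synthA_AA_2011,African American,21,c0,245.0,22.0,58,,,,OD,Cirrus HD-OCT,TRUE
synthA_AA_2011,African American,21,p_sup,310.0,18.0,58,,,,OD,Cirrus HD-OCT,TRUE
synthA_AA_2011,African American,21,f_sup,272.0,16.0,58,,,,OD,Cirrus HD-OCT,TRUE
synthB_AA_2014,African American,28.9,c0,240.0,20.0,134,,,,unspecified,Spectralis,TRUE
synthB_AA_2014,African American,28.9,p_sup,306.0,17.0,134,,,,unspecified,Spectralis,TRUE
synthB_AA_2014,African American,28.9,f_sup,268.0,15.0,134,,,,unspecified,Spectralis,TRUE
synthC_AA_2016,African American,36.2,c0,232.0,,88,227.6,236.4,,both,Cirrus HD-OCT,TRUE
synthC_AA_2016,African American,36.2,p_sup,298.0,,88,294.2,301.8,,both,Cirrus HD-OCT,TRUE
synthD_AA_2010,African American,47.7,c0,228.0,21.0,61,,,,OD,Stratus OCT,TRUE
synthD_AA_2010,African American,47.7,p_sup,294.0,19.0,61,,,,OD,Stratus OCT,TRUE
synthD_AA_2010,African American,47.7,f_sup,259.0,15.0,61,,,,OD,Stratus OCT,TRUE
synthE_AA_2013,African American,49,c0,226.0,,75,,,2.3,OS,Cirrus HD-OCT,TRUE
synthE_AA_2013,African American,49,p_sup,292.0,,75,,,2.1,OS,Cirrus HD-OCT,TRUE
synthF_ZA_2019,Black South African,33.5,c0,251.0,24.0,96,,,,OD,Spectralis,TRUE
synthF_ZA_2019,Black South African,33.5,p_sup,312.0,20.0,96,,,,OD,Spectralis,TRUE
synthG_noage,African American,,c0,238.0,19.0,52,,,,OD,Cirrus HD-OCT,TRUE
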