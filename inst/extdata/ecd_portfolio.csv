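arm_id,study_label,country,study_year,year_imputed,total_cost,per_child_local,per_child_standardized,league_eligible,domain,subgroup,estimate,lower,upper,significant
aboud_akhter_2011,"Aboud and Akhter, 2011",Bangladesh,2008,FALSE,13151,69,99,TRUE,cognitive,,0.40,0.10,0.69,TRUE
aboud_2013_gs,"Aboud et al, 2013 (Group sessions)",Bangladesh,2011,FALSE,NA,6,41,TRUE,cognitive,,0.67,0.48,0.86,TRUE
aboud_2013_gs,"Aboud et al, 2013 (Group sessions)",Bangladesh,2011,FALSE,NA,6,41,TRUE,expressive_language,,0.97,0.82,1.21,TRUE
aboud_2013_gs,"Aboud et al, 2013 (Group sessions)",Bangladesh,2011,FALSE,NA,6,41,TRUE,receptive_language,,0.85,0.64,1.03,TRUE
aboud_2013_hv,"Aboud et al, 2013 (Home visits)",Bangladesh,2011,FALSE,NA,1,24,TRUE,cognitive,,0.67,0.48,0.86,TRUE
aboud_2013_hv,"Aboud et al, 2013 (Home visits)",Bangladesh,2011,FALSE,NA,1,24,TRUE,expressive_language,,0.97,0.82,1.21,TRUE
aboud_2013_hv,"Aboud et al, 2013 (Home visits)",Bangladesh,2011,FALSE,NA,1,24,TRUE,receptive_language,,0.85,0.64,1.03,TRUE
boivin_2013,"Boivin et al, 2013",Uganda,2012,TRUE,39617,660,992,FALSE,cognitive,,0.03,-0.33,0.40,FALSE
boivin_2013,"Boivin et al, 2013",Uganda,2012,TRUE,39617,660,992,FALSE,expressive_language,,0.39,0.02,0.75,TRUE
boivin_2013,"Boivin et al, 2013",Uganda,2012,TRUE,39617,660,992,FALSE,fine_motor,,0.11,-0.25,0.47,FALSE
boivin_2013,"Boivin et al, 2013",Uganda,2012,TRUE,39617,660,992,FALSE,receptive_language,,0.44,0.07,0.81,TRUE
carlo_2003,"Carlo et al, 2003",India/Pakistan/Zambia,2007-2011,FALSE,20487,347,1256,FALSE,cognitive,non-resuscitated,0.23,-0.07,0.53,FALSE
carlo_2003,"Carlo et al, 2003",India/Pakistan/Zambia,2007-2011,FALSE,20487,347,1256,FALSE,cognitive,resuscitated,0.37,0.01,0.72,TRUE
eickmann_2003,"Eickmann et al, 2003",Brazil,1999,FALSE,16636,252,228,TRUE,cognitive,,0.81,0.46,1.16,TRUE
gardner_2005,"Gardner et al, 2005",Jamaica,2004,TRUE,38333,782,1282,FALSE,cognitive,,0.32,-0.05,0.70,FALSE
gardner_2005,"Gardner et al, 2005",Jamaica,2004,TRUE,38333,782,1282,FALSE,fine_motor,,0.16,-0.22,0.53,FALSE
gardner_2005,"Gardner et al, 2005",Jamaica,2004,TRUE,38333,782,1282,FALSE,language,,0.55,0.16,0.93,TRUE
hamadani_2006,"Hamadani et al, 2006",Bangladesh,2000-2002,FALSE,16801,183,1357,TRUE,cognitive,,0.33,0.04,0.61,TRUE
jin_2007,"Jin et al, 2007",China,2003,FALSE,828,17,62,TRUE,cognitive,,0.48,0.06,0.91,TRUE
jin_2007,"Jin et al, 2007",China,2003,FALSE,828,17,62,TRUE,language,,0.51,0.08,0.94,TRUE
lozoff_2010,"Lozoff et al, 2010",Chile,1991-1995,FALSE,167228,2172,3519,TRUE,cognitive,iron-deficient,1.80,1.21,2.18,TRUE
lozoff_2010,"Lozoff et al, 2010",Chile,1991-1995,FALSE,167228,2172,3519,TRUE,cognitive,non-iron-deficient,-0.41,-0.82,0.00,FALSE
nahar_2009,"Nahar et al, 2009",Bangladesh,2008,TRUE,3324,101,582,TRUE,cognitive,,0.84,0.35,1.33,TRUE
nair_2009,"Nair et al, 2009",India,2008,TRUE,1690,5,18,TRUE,cognitive,,0.21,0.06,0.35,TRUE
powell_2004,"Powell et al, 2004",Jamaica,2003,TRUE,50753,781,1290,TRUE,cognitive,,0.87,0.87,1.23,TRUE
powell_2004,"Powell et al, 2004",Jamaica,2003,TRUE,50753,781,1290,TRUE,fine_motor,,0.71,0.35,1.07,TRUE
powell_2004,"Powell et al, 2004",Jamaica,2003,TRUE,50753,781,1290,TRUE,language,,0.77,0.41,1.13,TRUE
vazir_2013,"Vazir et al, 2013",India,2012,TRUE,22534,147,418,TRUE,cognitive,,0.36,0.14,0.57,TRUE
walker_2004,"Walker et al, 2004",Jamaica,2003,TRUE,28218,448,735,FALSE,cognitive,,0.42,0.07,0.77,TRUE
walker_2004,"Walker et al, 2004",Jamaica,2003,TRUE,28218,448,735,FALSE,language,,0.00,-0.34,0.34,FALSE
yousafzai_2014,"Yousafzai et al, 2014",Pakistan,2009-2012,FALSE,48816,134,134,TRUE,cognitive,,0.60,0.45,0.76,TRUE
yousafzai_2014,"Yousafzai et al, 2014",Pakistan,2009-2012,FALSE,48816,134,134,TRUE,language,,0.70,0.45,0.75,TRUE
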