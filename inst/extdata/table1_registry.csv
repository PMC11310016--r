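trial_id,cancer_type,regimen,drug_class,control_type,assay_clone,scoring_method,n_low_pdl1,n_total,pct_printed,ipd_available
KEYNOTE-407,NSCLC,combination,anti-PD-1,placebo_chemo,22C3,TPS,194,559,34.7,TRUE
IMpower150,NSCLC,combination,anti-PD-L1,targeted_chemo,SP142,TPS&IPS,338,800,42.2,TRUE
CheckMate 214,RCC,combination,anti-PD-1,targeted,28-8,TPS,562,839,67.0,TRUE
IMmotion151,RCC,combination,anti-PD-L1,targeted,SP142,IPS,553,915,60.4,TRUE
IMpower130,NSCLC,combination,anti-PD-L1,chemo,SP142,TPS&IPS,356,723,49.2,FALSE
JAVELIN Renal 101,RCC,combination,anti-PD-L1,targeted,SP263,IPS,326,886,36.8,TRUE
IMvigor130,UC,combination,anti-PD-L1,placebo_chemo,SP142,IPS,392,1213,32.3,FALSE
IMspire150,melanoma,combination,anti-PD-L1,targeted,SP142,IPS,171,514,33.3,FALSE
IMpower131,NSCLC,combination,anti-PD-L1,chemo,SP142,TPS&IPS,331,683,48.5,FALSE
KEYNOTE-426,RCC,combination,anti-PD-1,targeted,22C3,CPS,321,861,37.3,FALSE
KEYNOTE-604,SCLC,combination,anti-PD-1,placebo_chemo,22C3,CPS,174,453,38.4,FALSE
IMpassion130,TNBC,combination,anti-PD-L1,placebo_chemo,SP142,IPS,533,902,61.3,TRUE
CheckMate 649,GC,combination,anti-PD-1,chemo,28-8,CPS,342,2394,14.3,TRUE
IMpower133,SCLC,combination,anti-PD-L1,placebo_chemo,SP263,TPS&IPS,65,403,16.2,TRUE
ESCORT-1st,ESCC,combination,anti-PD-1,placebo_chemo,28-8,TPS,256,598,43.0,TRUE
NCT03581786,NPC,combination,anti-PD-1,placebo_chemo,JS311,TPS&IPS,45,289,15.6,TRUE
IMpassion131,TNBC,combination,anti-PD-L1,placebo_chemo,SP142,IPS,359,651,55.1,TRUE
JAVELIN Gastric 100,GC,mono,anti-PD-L1,chemo,22C3,TPS,362,499,72.5,TRUE
JAVELIN Ovarian 100,OC,combination,anti-PD-L1,chemo,SP263,TPS&IPS,326,998,32.7,TRUE
IMagyn050,OC,combination,anti-PD-L1,targeted_chemo,SP142,IPS,517,1301,39.7,TRUE
IMpower132,NSCLC,combination,anti-PD-L1,chemo,SP142,TPS&IPS,163,578,28.2,TRUE
CheckMate 451,SCLC,combination,anti-PD-1,placebo,28-8,CPS,191,834,22.9,TRUE
CheckMate 9LA,NSCLC,combination,anti-PD-1,chemo,28-8,TPS,264,719,36.7,TRUE
KEYNOTE-189,NSCLC,combination,anti-PD-1,placebo_chemo,22C3,TPS,190,616,30.8,TRUE
TASUKI-52,NSCLC,combination,anti-PD-1,placebo_chemo,28-8,TPS,240,750,32.0,TRUE
CameL,NSCLC,combination,anti-PD-1,chemo,22C3,TPS,67,402,16.7,TRUE
CLEAR,RCC,combination,anti-PD-1,targeted,22C3,CPS,215,612,35.1,FALSE
KEYNOTE-361,UC,mono,anti-PD-1,chemo,22C3,CPS,341,659,51.7,FALSE
KEYNOTE-590,ESCC,combination,anti-PD-1,placebo_chemo,22C3,CPS,347,749,46.3,TRUE
KEYNOTE-048,HNSCC,combination,anti-PD-1,targeted_chemo,22C3,CPS,128,882,14.5,TRUE
KEYNOTE-355,TNBC,combination,anti-PD-1,placebo_chemo,22C3,CPS,211,847,24.9,TRUE
CheckMate 648,ESCC,combination,anti-PD-1,chemo,28-8,TPS,497,970,51.2,TRUE
CheckMate 227,NSCLC,combination,anti-PD-1,chemo,28-8,TPS,550,1739,31.6,TRUE
CheckMate 743,MPM,combination,anti-PD-1,chemo,28-8,TPS,135,605,22.3,TRUE
PACIFIC,NSCLC,mono,anti-PD-L1,crt_placebo,SP263,TPS,148,713,20.8,TRUE
CheckMate 067,melanoma,combination,anti-PD-1,targeted,28-8,TPS,353,945,35.4,TRUE
CheckMate 459,HCC,mono,anti-PD-1,targeted,28-8,TPS,595,743,80.1,TRUE
GEMSTONE-302,NSCLC,combination,anti-PD-L1,placebo_chemo,SP263,TPS,188,479,39.2,TRUE
IMbrave150,HCC,combination,anti-PD-L1,targeted,SP142,TPS&IPS,77,503,15.3,FALSE
EMPOWER-Lung 3,NSCLC,combination,anti-PD-L1,placebo_chemo,SP263,TPS,139,466,29.8,FALSE
ATTRACTION-4,GC,combination,anti-PD-1,placebo_chemo,28-8,TPS,610,724,84.2,FALSE
ORIENT-15,ESCC,combination,anti-PD-1,placebo_chemo,22C3,TPS,297,659,45.1,TRUE
CheckMate 9ER,RCC,combination,anti-PD-1,targeted,28-8,TPS,472,651,72.5,FALSE
CAPSTONE-1,SCLC,combination,anti-PD-L1,placebo_chemo,22C3,TPS,396,462,85.7,FALSE
ASTRUM-005,SCLC,combination,anti-PD-1,placebo_chemo,22C3,TPS,469,585,81.2,FALSE
POSEIDON,NSCLC,combination,anti-PD-L1,chemo,SP263,TPS,368,1013,36.3,FALSE
COMBI-i,melanoma,combination,anti-PD-1,targeted,28-8,TPS,213,532,40.0,TRUE
JUPITER-06,ESCC,combination,anti-PD-1,placebo_chemo,JS311,TPS,193,295,65.4,TRUE
NEPTUNE,NSCLC,combination,anti-PD-L1,chemo,SP263,IPS,195,823,23.7,TRUE
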