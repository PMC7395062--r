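name,target_complex,cas,mol_weight,clogp,subset_flag,sim_mechanism,sim_potency_log10M
Capsaicin,CI,404-86-4,305.20,3.64,TRUE,inhibitor,-3.59
Deguelin,CI,522-17-8,394.14,4.26,TRUE,inhibitor,-6.98
Fenazaquin,CI,120928-09-8,306.17,5.51,FALSE,inhibitor,-6.74
Fenpyroximate,CI,134098-61-6,421.20,5.01,TRUE,inhibitor,-7.72
Pyridaben,CI,96489-71-3,364.14,5.24,FALSE,inhibitor,-7.37
Pyrimidifen,CI,105779-78-0,377.19,5.03,TRUE,inhibitor,-8.15
Rotenone,CI,83-79-4,394.14,4.10,TRUE,inhibitor,-7.48
Tebufenpyrad,CI,119168-77-3,333.16,4.93,TRUE,inhibitor,-5.26
Carboxin,CII,5234-68-4,235.07,2.22,TRUE,inhibitor,-4.63
Fenfuram,CII,24691-80-3,201.08,2.24,FALSE,inhibitor,-3.00
Flutolanil,CII,66332-96-5,323.11,3.70,FALSE,inhibitor,-4.16
Mepronil,CII,55814-41-0,269.14,3.90,TRUE,inhibitor,-3.75
Thifluzamide,CII,130000-40-7,525.84,5.05,TRUE,inhibitor,-4.71
Antimycin A,CIII,1397-94-0,548.27,4.41,TRUE,inhibitor,-7.72
Azoxystrobin,CIII,131860-33-8,403.12,2.50,TRUE,inhibitor,-4.77
Cyazofamid,CIII,120116-88-3,324.04,3.20,TRUE,uncoupler,-5.88
Fenamidone,CIII,161326-34-7,311.11,3.72,FALSE,inhibitor,-4.71
Kresoxim-methyl,CIII,143390-89-0,313.13,3.40,FALSE,inhibitor,-5.21
Picoxystrobin,CIII,117428-22-5,367.10,3.81,TRUE,inhibitor,-5.40
Pyraclostrobin,CIII,175013-18-0,387.10,3.99,TRUE,inhibitor,-6.41
Trifloxystrobin,CIII,141517-21-7,408.13,4.50,FALSE,inhibitor,-5.27
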