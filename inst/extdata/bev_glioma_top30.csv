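soc,pt,a,b,c,d,ror,ror_l,ror_u,prr,chi2,ic,ic025
GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS,DEATH,547,13548,504,51929,4.16,3.68,4.70,4.04,609.01,1.30,1.14
GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS,DISEASE PROGRESSION,456,13639,1101,51332,1.56,1.40,1.74,1.54,62.65,0.47,0.31
"INJURY, POISONING AND PROCEDURAL COMPLICATIONS",OFF LABEL USE,422,13673,936,51497,1.70,1.51,1.91,1.68,81.18,0.55,0.39
GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS,FATIGUE,301,13794,640,51793,1.77,1.54,2.03,1.75,66.68,0.59,0.40
VASCULAR DISORDERS,HYPERTENSION,234,13861,175,52258,5.04,4.14,6.14,4.97,319.87,1.43,1.20
NERVOUS SYSTEM DISORDERS,HEADACHE,216,13879,513,51920,1.58,1.34,1.85,1.57,31.47,0.48,0.26
GASTROINTESTINAL DISORDERS,NAUSEA,161,13934,638,51795,0.94,0.79,1.12,0.94,0.52,-0.07,-0.32
BLOOD AND LYMPHATIC SYSTEM DISORDERS,THROMBOCYTOPENIA,160,13935,1015,51418,0.58,0.49,0.69,0.59,41.04,-0.64,-0.88
"NEOPLASMS BENIGN, MALIGNANT AND UNSPECIFIED (INCL CYSTS AND POLYPS)",GLIOBLASTOMA,153,13942,312,52121,1.83,1.51,2.23,1.82,38.50,0.64,0.37
INVESTIGATIONS,PLATELET COUNT DECREASED,150,13945,393,52040,1.42,1.18,1.72,1.42,13.59,0.38,0.12
GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS,ASTHENIA,148,13947,400,52033,1.38,1.14,1.67,1.38,11.21,0.35,0.08
NERVOUS SYSTEM DISORDERS,SEIZURE,137,13958,518,51915,0.98,0.81,1.19,0.98,0.03,-0.02,-0.29
"RESPIRATORY, THORACIC AND MEDIASTINAL DISORDERS",PULMONARY EMBOLISM,130,13965,449,51984,1.08,0.89,1.31,1.08,0.56,0.08,-0.20
GASTROINTESTINAL DISORDERS,DIARRHOEA,129,13966,434,51999,1.11,0.91,1.35,1.11,1.01,0.11,-0.17
PSYCHIATRIC DISORDERS,CONFUSIONAL STATE,127,13968,341,52092,1.39,1.13,1.70,1.39,9.99,0.36,0.07
GASTROINTESTINAL DISORDERS,VOMITING,119,13976,603,51830,0.73,0.60,0.89,0.73,9.68,-0.36,-0.65
GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS,PYREXIA,118,13977,678,51755,0.64,0.53,0.78,0.65,19.53,-0.52,-0.80
INVESTIGATIONS,BLOOD PRESSURE INCREASED,115,13980,80,52353,5.38,4.04,7.17,5.35,167.24,1.48,1.14
"NEOPLASMS BENIGN, MALIGNANT AND UNSPECIFIED (INCL CYSTS AND POLYPS)",NEOPLASM PROGRESSION,110,13985,377,52056,1.09,0.88,1.34,1.09,0.58,0.09,-0.21
"INJURY, POISONING AND PROCEDURAL COMPLICATIONS",FALL,107,13988,303,52130,1.32,1.05,1.64,1.31,5.96,0.30,-0.01
RENAL AND URINARY DISORDERS,PROTEINURIA,106,13989,34,52399,11.68,7.93,17.19,11.60,249.81,1.84,1.47
GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS,DRUG INEFFECTIVE,105,13990,622,51811,0.63,0.51,0.77,0.63,20.02,-0.55,-0.85
"INJURY, POISONING AND PROCEDURAL COMPLICATIONS",INTENTIONAL PRODUCT USE ISSUE,98,13997,155,52278,2.36,1.83,3.04,2.35,46.84,0.87,0.53
INVESTIGATIONS,WEIGHT INCREASED,96,13999,127,52306,2.82,2.17,3.68,2.81,64.05,1.02,0.67
VASCULAR DISORDERS,DEEP VEIN THROMBOSIS,96,13999,284,52149,1.26,1.00,1.59,1.26,3.80,0.25,-0.07
INVESTIGATIONS,WEIGHT DECREASED,94,14001,187,52246,1.88,1.46,2.40,1.87,25.42,0.66,0.32
NERVOUS SYSTEM DISORDERS,HEMIPARESIS,92,14003,274,52159,1.25,0.99,1.59,1.25,3.44,0.25,-0.09
MUSCULOSKELETAL AND CONNECTIVE TISSUE DISORDERS,MUSCULAR WEAKNESS,87,14008,189,52244,1.72,1.33,2.21,1.71,17.73,0.57,0.22
BLOOD AND LYMPHATIC SYSTEM DISORDERS,NEUTROPENIA,86,14009,563,51870,0.57,0.45,0.71,0.57,24.72,-0.68,-1.01
GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS,GENERAL PHYSICAL HEALTH DETERIORATION,85,14010,218,52215,1.45,1.13,1.87,1.45,8.59,0.40,0.05
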