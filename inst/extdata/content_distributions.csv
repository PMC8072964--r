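compound,part,n_detected,n_total,mean,median,sd,min,max
D-Limonene,tobacco,7,54,8.50,3.02,10.93,0.33,30.49
D-Limonene,filter_tip,11,54,8.85,1.24,14.68,0.26,45.62
D-Limonene,capsule,40,42,265.07,30.87,379.35,0.43,1578.66
Linalool,tobacco,21,54,0.60,0.06,1.68,0.04,7.83
Linalool,filter_tip,44,54,1.92,0.08,6.85,0.03,40.69
Linalool,capsule,41,42,33.31,4.39,63.04,0.03,299.91
Methyl 2-octynoate,tobacco,0,54,,,,,
Methyl 2-octynoate,filter_tip,0,54,,,,,
Methyl 2-octynoate,capsule,0,42,,,,,
Citral,tobacco,54,54,0.29,0.21,0.49,0.11,3.87
Citral,filter_tip,16,54,7.67,0.09,28.57,0.07,118.27
Citral,capsule,29,42,24.62,2.50,64.42,0.04,255.34
Citronellol,tobacco,0,54,,,,,
Citronellol,filter_tip,2,54,1.89,1.89,1.36,0.53,3.25
Citronellol,capsule,25,42,2.81,0.44,5.45,0.14,25.49
Geraniol,tobacco,0,54,,,,,
Geraniol,filter_tip,6,54,1.30,0.74,1.08,0.35,3.14
Geraniol,capsule,26,42,9.74,1.10,25.91,0.09,130.26
alpha-Isomethyl ionone,tobacco,12,54,0.02,0.02,0.00,0.02,0.03
alpha-Isomethyl ionone,filter_tip,8,54,0.03,0.02,0.01,0.02,0.05
alpha-Isomethyl ionone,capsule,1,42,0.02,0.02,0.00,0.02,0.02
Benzyl alcohol,tobacco,52,54,2.80,0.74,5.52,0.09,28.97
Benzyl alcohol,filter_tip,54,54,18.43,1.32,36.17,0.26,166.73
Benzyl alcohol,capsule,21,42,30.78,0.16,93.53,0.05,330.43
Hydroxycitronellal,tobacco,0,54,,,,,
Hydroxycitronellal,filter_tip,0,54,,,,,
Hydroxycitronellal,capsule,0,42,,,,,
Methyl eugenol,tobacco,0,54,,,,,
Methyl eugenol,filter_tip,1,54,0.03,0.03,0.00,0.03,0.03
Methyl eugenol,capsule,12,42,0.06,0.02,0.09,0.01,0.32
Cinnamaldehyde,tobacco,0,54,,,,,
Cinnamaldehyde,filter_tip,7,54,0.36,0.14,0.40,0.05,1.25
Cinnamaldehyde,capsule,10,42,43.56,0.05,69.30,0.01,182.40
Lilial,tobacco,0,54,,,,,
Lilial,filter_tip,0,54,,,,,
Lilial,capsule,0,42,,,,,
Eugenol,tobacco,4,54,0.14,0.12,0.06,0.08,0.23
Eugenol,filter_tip,1,54,1.00,1.00,0.00,1.00,1.00
Eugenol,capsule,27,42,0.24,0.24,0.17,0.03,0.74
alpha-Amylcinnamaldehyde,tobacco,0,54,,,,,
alpha-Amylcinnamaldehyde,filter_tip,0,54,,,,,
alpha-Amylcinnamaldehyde,capsule,0,42,,,,,
Anise alcohol,tobacco,4,54,0.37,0.33,0.14,0.22,0.58
Anise alcohol,filter_tip,2,54,0.46,0.46,0.05,0.41,0.51
Anise alcohol,capsule,0,42,,,,,
Cinnamyl alcohol,tobacco,0,54,,,,,
Cinnamyl alcohol,filter_tip,0,54,,,,,
Cinnamyl alcohol,capsule,3,42,0.25,0.31,0.13,0.07,0.36
Isoeugenol,tobacco,5,54,0.34,0.26,0.18,0.17,0.66
Isoeugenol,filter_tip,0,54,,,,,
Isoeugenol,capsule,5,42,0.37,0.07,0.43,0.01,1.03
alpha-Hexylcinnamaldehyde,tobacco,0,54,,,,,
alpha-Hexylcinnamaldehyde,filter_tip,0,54,,,,,
alpha-Hexylcinnamaldehyde,capsule,0,42,,,,,
Farnesol,tobacco,0,54,,,,,
Farnesol,filter_tip,0,54,,,,,
Farnesol,capsule,2,42,0.22,0.22,0.00,0.22,0.22
Coumarin,tobacco,0,54,,,,,
Coumarin,filter_tip,0,54,,,,,
Coumarin,capsule,0,42,,,,,
HICC,tobacco,0,54,,,,,
HICC,filter_tip,0,54,,,,,
HICC,capsule,0,42,,,,,
alpha-Amylcinnamyl alcohol,tobacco,0,54,,,,,
alpha-Amylcinnamyl alcohol,filter_tip,0,54,,,,,
alpha-Amylcinnamyl alcohol,capsule,0,42,,,,,
Benzyl benzoate,tobacco,31,54,0.41,0.06,1.12,0.03,5.18
Benzyl benzoate,filter_tip,9,54,0.18,0.08,0.14,0.05,0.45
Benzyl benzoate,capsule,7,42,0.20,0.12,0.14,0.02,0.38
Benzyl salicylate,tobacco,2,54,0.51,0.51,0.04,0.47,0.56
Benzyl salicylate,filter_tip,0,54,,,,,
Benzyl salicylate,capsule,0,42,,,,,
Benzyl cinnamate,tobacco,0,54,,,,,
Benzyl cinnamate,filter_tip,1,54,1.18,1.18,0.00,1.18,1.18
Benzyl cinnamate,capsule,6,42,2.08,0.04,2.91,0.02,6.32
Menthol,tobacco,53,54,191.07,1.34,448.81,0.05,1868.14
Menthol,filter_tip,53,54,417.05,2.39,863.24,0.11,3011.88
Menthol,capsule,42,42,1518.22,1378.95,450.78,689.47,2419.50
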