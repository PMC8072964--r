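compound,matrix,lod_ng_per_ml
D-Limonene,solvent,0.12
Linalool,solvent,0.339
Methyl 2-octynoate,solvent,0.558
Citral,solvent,0.776
Citronellol,solvent,0.995
Geraniol,solvent,1.214
alpha-Isomethyl ionone,solvent,0.594
Benzyl alcohol,solvent,1.485
Hydroxycitronellal,solvent,1.87
Methyl eugenol,solvent,0.297
Cinnamaldehyde,solvent,0.297
Lilial,solvent,2.527
Eugenol,solvent,0.891
alpha-Amylcinnamaldehyde,solvent,2.964
Anise alcohol,solvent,3.183
Cinnamyl alcohol,solvent,2.079
Isoeugenol,solvent,0.297
alpha-Hexylcinnamaldehyde,solvent,3.84
Farnesol,solvent,4.058
Coumarin,solvent,4.277
HICC,solvent,4.496
alpha-Amylcinnamyl alcohol,solvent,4.715
Benzyl benzoate,solvent,0.594
Benzyl salicylate,solvent,5.152
Benzyl cinnamate,solvent,0.594
Menthol,solvent,5.59
D-Limonene,tobacco,0.49
Linalool,tobacco,0.475
Methyl 2-octynoate,tobacco,1.076
Citral,tobacco,1.307
Citronellol,tobacco,1.661
Geraniol,tobacco,1.954
alpha-Isomethyl ionone,tobacco,0.238
Benzyl alcohol,tobacco,1.069
Hydroxycitronellal,tobacco,2.832
Methyl eugenol,tobacco,3.125
Cinnamaldehyde,tobacco,3.418
Lilial,tobacco,3.711
Eugenol,tobacco,0.95
alpha-Amylcinnamaldehyde,tobacco,4.296
Anise alcohol,tobacco,2.614
Cinnamyl alcohol,tobacco,4.882
Isoeugenol,tobacco,2.02
alpha-Hexylcinnamaldehyde,tobacco,5.468
Farnesol,tobacco,5.76
Coumarin,tobacco,6.053
HICC,tobacco,6.346
alpha-Amylcinnamyl alcohol,tobacco,6.639
Benzyl benzoate,tobacco,0.356
Benzyl salicylate,tobacco,5.584
Benzyl cinnamate,tobacco,7.517
Menthol,tobacco,0.594
D-Limonene,filter_tip,0.49
Linalool,filter_tip,0.356
Methyl 2-octynoate,filter_tip,0.898
Citral,filter_tip,0.832
Citronellol,filter_tip,1.306
Geraniol,filter_tip,1.51
alpha-Isomethyl ionone,filter_tip,0.238
Benzyl alcohol,filter_tip,1.918
Hydroxycitronellal,filter_tip,2.122
Methyl eugenol,filter_tip,0.356
Cinnamaldehyde,filter_tip,0.594
Lilial,filter_tip,2.734
Eugenol,filter_tip,2.938
alpha-Amylcinnamaldehyde,filter_tip,3.142
Anise alcohol,filter_tip,3.346
Cinnamyl alcohol,filter_tip,3.55
Isoeugenol,filter_tip,3.754
alpha-Hexylcinnamaldehyde,filter_tip,3.958
Farnesol,filter_tip,4.162
Coumarin,filter_tip,4.366
HICC,filter_tip,4.57
alpha-Amylcinnamyl alcohol,filter_tip,4.774
Benzyl benzoate,filter_tip,0.594
Benzyl salicylate,filter_tip,5.182
Benzyl cinnamate,filter_tip,5.386
Menthol,filter_tip,1.307
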