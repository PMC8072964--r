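compound,stat,content_ug_per_cigarette
D-Limonene,average,119.47
D-Limonene,maximum,818.21
Linalool,average,23.22
Linalool,maximum,301.86
Citral,average,15.12
Citral,maximum,255.67
Citronellol,average,1.60
Citronellol,maximum,26.15
Geraniol,average,4.27
Geraniol,maximum,130.58
alpha-Isomethyl ionone,average,0.04
alpha-Isomethyl ionone,maximum,0.08
Benzyl alcohol,average,33.10
Benzyl alcohol,maximum,474.41
Methyl eugenol,average,0.05
Methyl eugenol,maximum,0.35
Cinnamaldehyde,average,8.15
Cinnamaldehyde,maximum,182.95
Eugenol,average,0.27
Eugenol,maximum,1.38
Anise alcohol,average,0.33
Anise alcohol,maximum,1.16
Cinnamyl alcohol,average,0.09
Cinnamyl alcohol,maximum,0.43
Isoeugenol,average,0.33
Isoeugenol,maximum,1.27
Farnesol,average,0.86
Farnesol,maximum,1.12
Benzyl benzoate,average,0.33
Benzyl benzoate,maximum,5.24
Benzyl salicylate,average,0.61
Benzyl salicylate,maximum,0.82
Benzyl cinnamate,average,0.33
Benzyl cinnamate,maximum,6.41
Menthol,average,1565.01
Menthol,maximum,7870.83
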