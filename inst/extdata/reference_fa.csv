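name,fa_obs
Amiloride,0.53
Amprenavir,0.76
Antipyrine,0.98
Azithromycin,0.43
Biperiden,1.0
Boceprevir,0.92
Bosentan,0.70
Bupropion,0.88
Caffeine,1.0
Cetirizine,0.73
Clozapine,0.99
Corticosterone,1.0
Diclofenac,0.97
Dipyridamole,0.56
Doxepin,0.76
Flecainide,0.82
Furosemide,0.61
Gliquidone,0.95
Hydroxychloroquine,0.90
Imatinib,0.90
Indinavir,0.63
Ketoconazole,0.76
Lamotrigine,0.98
Lenalidomide,0.90
Loperamide,0.52
Loratadine,0.90
Methotrexate,0.64
Metoclopramide,0.89
Mexiletine,0.99
Moclobemide,0.85
Naratriptan,0.70
Nicotine,1.0
Nimodipine,1.0
Nortriptyline,1.0
Ondansetron,1.0
Oseltamivir,0.75
Phenazopyridine,0.90
Phenytoin,0.93
Physostigmine,0.050
Pirenzepine,0.26
Propranolol,0.97
Ranitidine,0.56
Rifabutin,0.53
Riluzole,0.90
Risperidone,0.85
Rizatriptan,0.90
Rosiglitazone,1.0
Rosuvastatin,0.35
Roxithromycin,0.86
Selegiline,1.0
Sulfasalazine,0.33
Sumatriptan,0.58
Telmisartan,0.82
Trazodone,0.98
Trihexyphenidyl,1.0
Vardenafil,0.90
Venlafaxine,0.96
Verapamil,0.92
Vismodegib,0.69
Ziprasidone,0.63
Zolmitriptan,0.92
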