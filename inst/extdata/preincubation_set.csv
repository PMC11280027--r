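name,mw_lower,mw_upper,clogp_lower,clogp_upper,lipinski_class
Amiloride,230,230,-0.5,-0.5,Ro5
Cimetidine,252,252,-0.1,-0.1,Ro5
Carbamazepine,236,236,2.8,2.8,Ro5
Metoprolol,267,267,1.8,1.8,Ro5
Atenolol,266,266,0.4,0.4,Ro5
Quinidine,324,324,2.5,2.5,Ro5
Propranolol,259,259,2.6,2.6,Ro5
Verapamil,455,455,5,5,Ro5
Midazolam,326,326,3.3,3.3,Ro5
Prazosin,383,383,1.7,1.7,Ro5
Compound 1,700,,3,,bRo5
Compound 2,,700,3,,Ro5
Compound 3,700,,3,,bRo5
Compound 4,700,,,,bRo5
Compound 5,,700,3,,bRo5
Compound 6,700,,3,,bRo5
Compound 7,700,,,3,bRo5
Compound 8,700,,,3,bRo5
Compound 9,700,,3,,bRo5
Compound 10,700,,3,,bRo5
Compound 11,700,,,,bRo5
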