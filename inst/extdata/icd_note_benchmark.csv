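condition,n,icd_sensitivity,icd_specificity,note_sensitivity,note_specificity
aspergillosis,264,0.69,0.98,0.96,0.95
lupus,138,0.80,0.99,1.0,0.98
brain_death,209,0.04,0.96,1.0,0.94
meningitis,276,0.89,0.92,0.89,0.99
diabetes_insipidus,497,0.56,0.98,0.98,0.96
pulmonary_embolism,244,0.96,0.99,0.96,0.99
intestinal_volvulus,146,0.72,0.87,0.98,0.95
esophageal_varices,301,0.55,0.92,1.0,0.85
central_cord_syndrome,73,0.59,0.94,1.0,0.91
osteomyelitis,235,0.53,0.74,0.98,0.97
endocarditis,417,0.85,0.97,1.0,0.90
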