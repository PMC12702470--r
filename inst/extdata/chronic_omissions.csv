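condition,chronic_omissions
aspergillosis,2
diabetes_insipidus,1
intestinal_volvulus,2
central_cord_syndrome,2
endocarditis,16
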