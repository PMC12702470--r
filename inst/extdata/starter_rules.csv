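rule_id,cue,side,max_gap,category,source,created_from
acute-01,currently with,before,5,ACUTE_PRESENT,general,
acute-02,admitted with,before,5,ACUTE_PRESENT,general,
acute-03,chief complaint,before,5,ACUTE_PRESENT,general,
hist-01,history of,before,5,HISTORICAL_CHRONIC,general,
hist-02,previous hospitalization for,before,5,HISTORICAL_CHRONIC,general,
hist-03,as a child,before,5,HISTORICAL_CHRONIC,general,
neg-01,no evidence of,before,5,NEGATED,general,
neg-02,negative for,before,5,NEGATED,general,
neg-03,doubt,before,5,NEGATED,general,
neg-04,without,before,5,NEGATED,general,
eval-01,may have,before,5,UNDER_EVALUATION,general,
eval-02,suspected,before,5,UNDER_EVALUATION,general,
eval-03,assessment for,before,5,UNDER_EVALUATION,general,
diff-01,<term> xray,either,2,DIFFERENT_MEANING,general,decubitus_ulcer
diff-02,joint <term>,either,2,DIFFERENT_MEANING,general,aspiration_pneumonia
diff-03,<term> anticoagulant,either,2,DIFFERENT_MEANING,general,lupus
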