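cohort,total_visits,admitted_visits,printed_admission_pct
adult,160016,47283,29.5
pediatric,22222,3617,16.3
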