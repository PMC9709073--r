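filter funnel:
  reports_read               225
  deduplicated_cases         200
  target_cohort              25
  pt_terms                   34
  pt_all_four                0
  soc_terms                  12
  onset_records              13
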