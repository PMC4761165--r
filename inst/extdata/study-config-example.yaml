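# Example study configuration. Omitted keys fall back to package defaults.
study_start: "2010-01-01"
study_end: "2011-12-31"
lookback_days: 365
followup_days: 365
adult_age_min: 18
national_population: 65026885
code_set:
  dvt_codes: ["I80.1-9", "I82.1-9"]
  pe_codes: ["I26.0", "I26.9"]
rule:
  heparin_window_days: 7
  vka_window_days: 7
  migration_window_days: 30
  comm_to_hosp_window_days: 30
  recurrence_gap_days: 30
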