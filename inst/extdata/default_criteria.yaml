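# Acceptance criteria and risk-category cutoffs used throughout the
# validation suite. Any key omitted keeps the package default.
loq_cv_max: 10            # intra-plate CV ceiling (%) at the LoQ levels
loq_recovery_low: 80      # recovery band (%) at the LoQ levels
loq_recovery_high: 120
lloq_blank_signal_ratio_min: 3    # LLoQ mean signal >= 3x blank signal
uloq_top_signal_fraction_max: 0.70  # ULoQ mean signal <= 70% of top calibrator
adl_delta: 15             # allowable deviation from linearity (%)
risk_cutoff_low_max: 45   # scaled score <= 45 -> low risk
risk_cutoff_int_min: 50   # 50 <= score <= 85 -> intermediate risk
risk_cutoff_int_max: 85   # score > 85 -> high risk
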