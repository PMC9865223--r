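feature_set,oa_pct,kappa
optimal,98.41,0.98
time_series_ndvi,96.03,0.95
time_series_rvi,95.56,0.95
time_series_dvi,91.27,0.90
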