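{"weights":{"mean_local_skewness":1.13270577921234,"log_alpha_power":-2.43642758151094,"lambda":-0.0315703224184781,"fit_error":-0.0964536409022236,"range_within_pattern":-0.53845042839807,"current_density_norm":0.757014472690325},"bias":1.42032477553275,"feature_mean":{"mean_local_skewness":1.01818862049735,"log_alpha_power":-2.84554861886863,"lambda":0.862874290406458,"fit_error":0.381660087700238,"range_within_pattern":-0.176444350561353,"current_density_norm":-2.13282119608888},"feature_sd":{"mean_local_skewness":1.78860789568131,"log_alpha_power":1.18264611984479,"lambda":1.1339293842596,"fit_error":0.467791595695393,"range_within_pattern":0.361832326070803,"current_density_norm":0.249545383779903}}
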