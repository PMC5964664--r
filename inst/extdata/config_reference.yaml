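# Reference analysis configuration (mirrors analysis_config())
threshold: 20
scale: log_odds
continuous_fitter: GLS
firth: yes
mbn: yes
ci_level: 0.95
quadrature_nodes: 40
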