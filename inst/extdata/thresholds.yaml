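median_cut: 7
top_cut: 20
consensus_high: 0.70
discussion_high: 0.30
discussion_low: 0.30
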