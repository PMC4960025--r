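"n_pending","p_positive","positive_id","negative_id"
4,0.5,17,18
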