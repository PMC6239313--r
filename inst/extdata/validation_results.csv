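dataset,recall_pct,precision_pct,n_training_samples
JC77,91.7,50.5,1040
PAP,77.2,14.3,200
SO242,83.4,26.1,600
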