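tissue,f_ew,f_iw,f_nl,f_np,provenance
adipose,0.14,0.017,0.79,0.002,mechanistic tissue-composition compilations for partition-coefficient prediction
brain,0.16,0.62,0.039,0.0015,mechanistic tissue-composition compilations
heart,0.32,0.46,0.014,0.011,mechanistic tissue-composition compilations
kidney,0.27,0.48,0.021,0.016,mechanistic tissue-composition compilations
liver,0.16,0.57,0.035,0.025,mechanistic tissue-composition compilations
lung,0.34,0.45,0.022,0.013,mechanistic tissue-composition compilations
muscle,0.12,0.63,0.01,0.0072,mechanistic tissue-composition compilations
rest,0.3,0.45,0.02,0.01,lumped remainder; average of visceral tissue rows
skin,0.38,0.29,0.06,0.0044,mechanistic tissue-composition compilations
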