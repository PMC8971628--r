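model	lnL	neg2lnL	aic
sporadic	-8.3785	16.757	26.757
sporadic_residual	-6.75353	13.507	23.5071
mendelian_AD	-7.66576	15.3315	23.2215
mendelian_AR	-7.66575	15.332	23.2216
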