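level	term	df	ss	ms	f	r2	p
genus	PCR target region	1	0.20243	0.202433	8.3050	0.51946	0.0042
genus	PCR polymerase kit	1	0.05565	0.055651	2.2831	0.14281	0.0738
genus	Reference database	1	0.03411	0.034112	1.3995	0.08754	0.2941
genus	Residuals	4	0.09750	0.024375	NA	0.25019	NA
genus	Total	7	0.38970	NA	NA	1	NA
species	PCR target region	1	0.29283	0.292825	9.3314	0.55341	0.0036
species	PCR polymerase kit	1	0.04329	0.043285	1.3794	0.08180	0.3081
species	Reference database	1	0.06750	0.067499	2.1510	0.12757	0.1667
species	Residuals	4	0.12552	0.031381	NA	0.23722	NA
species	Total	7	0.52913	NA	NA	1	NA
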