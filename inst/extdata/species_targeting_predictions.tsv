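species	sequences	chloroplast_targeted	percent_chloroplast_targeted
Atr	26846	1833	6.83
Aam	27959	1324	4.74
Ath	35386	2826	7.99
Bdi	52972	4240	8.00
Fve	32831	2051	6.25
Gma	73320	5125	6.99
Mdo	74249	4665	6.28
Osa	49061	3417	6.96
Pvi	133775	10262	7.67
Ptr	73013	5741	7.86
Ppe	47089	3615	7.68
Sit	43001	3461	8.05
Sly	47205	1875	3.97
Sbi	34727	3918	11.28
Vvi	55564	3932	7.08
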