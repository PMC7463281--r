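study	n	SR	BM	T	ST
survey_01	416	0.135	0	0	0.865
survey_02	1071	0.100	0	0	0.900
survey_03	175	0.160	0	0	0.840
survey_04	224	0.138	0	0	0.862
survey_05	10495	0.149	0	0	0.851
survey_06	5753	0.096	0	0	0.904
survey_07	3866	0.124	0	0.001	0.875
survey_08	2214	0.140	0	0	0.860
survey_09	1561	0.195	0	0	0.805
survey_10	684	0.193	0.001	0.003	0.803
pooled	26459	0.13455	0.00004	0.00015	0.86526
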