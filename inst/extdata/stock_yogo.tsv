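n_endog	n_instruments	criterion	critical_value
1	3	bias_5	13.91
1	4	bias_5	16.85
1	5	bias_5	18.37
1	6	bias_5	19.28
1	7	bias_5	19.86
1	8	bias_5	20.25
1	3	bias_10	9.08
1	4	bias_10	10.27
1	5	bias_10	10.83
1	6	bias_10	11.12
1	7	bias_10	11.29
1	8	bias_10	11.39
1	3	bias_20	6.46
1	4	bias_20	6.71
1	5	bias_20	6.77
1	6	bias_20	6.76
1	7	bias_20	6.73
1	8	bias_20	6.69
1	3	bias_30	5.39
1	4	bias_30	5.34
1	5	bias_30	5.25
1	6	bias_30	5.15
1	7	bias_30	5.07
1	8	bias_30	4.99
1	1	size_10	16.38
1	2	size_10	19.93
1	3	size_10	22.30
1	4	size_10	24.58
1	5	size_10	26.87
1	6	size_10	29.18
1	7	size_10	31.50
1	8	size_10	33.84
1	1	size_15	8.96
1	2	size_15	11.59
1	3	size_15	12.83
1	4	size_15	13.96
1	5	size_15	15.09
1	6	size_15	16.23
1	7	size_15	17.38
1	8	size_15	18.54
1	1	size_20	6.66
1	2	size_20	8.75
1	3	size_20	9.54
1	4	size_20	10.26
1	5	size_20	10.98
1	6	size_20	11.72
1	7	size_20	12.48
1	8	size_20	13.24
1	1	size_25	5.53
1	2	size_25	7.25
1	3	size_25	7.80
1	4	size_25	8.31
1	5	size_25	8.84
1	6	size_25	9.38
1	7	size_25	9.93
1	8	size_25	10.50
2	4	bias_5	11.04
2	5	bias_5	13.97
2	6	bias_5	15.72
2	7	bias_5	16.88
2	8	bias_5	17.70
2	2	size_10	7.03
2	3	size_10	13.43
2	4	size_10	16.87
2	5	size_10	19.45
2	6	size_10	21.68
2	7	size_10	23.72
2	8	size_10	25.64
2	2	size_15	4.58
2	3	size_15	8.18
2	4	size_15	9.93
2	5	size_15	11.22
2	6	size_15	12.33
2	7	size_15	13.34
2	8	size_15	14.31
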