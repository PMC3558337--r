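partition	length_bx	length_pv	A_bx	A_pv	C_bx	C_pv	T_bx	T_pv	G_bx	G_pv	AT_bx	AT_pv
entire	14778	21656	31.8	31.8	5.4	9.8	51.7	42.1	11.1	16.3	83.5	73.9
pcg	10182	10002	27.1	26.7	6.3	8.7	53.4	48.4	13.2	16.2	80.5	75.1
pcg_pos1	3394	3334	28.5	27.6	6.6	9.0	46.8	43.0	18.1	20.4	75.3	70.6
pcg_pos2	3394	3334	19.2	18.3	10.4	12.5	55.7	51.8	14.7	17.4	74.9	70.1
pcg_pos3	3394	3334	33.5	34.4	1.9	4.4	57.7	50.3	6.8	10.9	91.2	84.7
rRNA	1648	1581	39.1	30.2	5.0	11.5	46.2	39.2	9.7	19.1	85.3	69.4
tRNA	1214	1216	39.1	35.0	4.9	6.9	45.6	42.2	10.5	16.0	84.7	77.2
NCR	1650	7748	47.7	37.4	0.7	11.3	51.0	35.5	0.7	15.8	98.7	72.9
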