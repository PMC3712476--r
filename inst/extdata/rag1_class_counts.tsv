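steps	nStates	simExpected	dpExpected
0	1	282	283.21
1	2	110.1	109.00
2	2	48.0	48.60
3	2	25.5	24.67
4	2	12.9	12.59
5	2	6.6	6.30
6	2	3.1	3.09
7-20	2	2.5	2.59
2	3	40.3	40.26
3	3	38.2	38.43
4	3	29.7	29.98
5	3	21.8	21.51
6	3	14.4	14.70
7	3	9.7	9.63
8	3	5.7	5.94
9	3	3.2	3.35
10-26	3	2.8	2.80
3-4	4	16.8	16.43
5	4	11.4	11.39
6	4	11	11.32
7	4	10.3	10.29
8	4	8.2	8.61
9	4	6.5	6.50
10	4	4.3	4.31
11-30	4	4.7	4.51
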