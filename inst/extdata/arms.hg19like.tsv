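chrom	arm	start	end
1	p	1	121500000
1	q	125000000	249250621
2	p	1	92300000
2	q	95300000	243199373
3	p	1	90500000
3	q	93500000	198022430
4	p	1	49700000
4	q	52700000	191154276
5	p	1	46100000
5	q	49400000	180915260
6	p	1	58700000
6	q	61700000	171115067
7	p	1	58000000
7	q	61700000	159138663
8	p	1	43100000
8	q	46100000	146364022
9	p	1	47300000
9	q	50700000	141213431
10	p	1	38000000
10	q	42300000	135534747
11	p	1	51600000
11	q	54700000	135006516
12	p	1	34800000
12	q	37900000	133851895
13	p	1	16000000
13	q	19000000	115169878
14	p	1	15600000
14	q	19100000	107349540
15	p	1	15800000
15	q	20700000	102531392
16	p	1	34600000
16	q	38600000	90354753
17	p	1	22200000
17	q	25800000	81195210
18	p	1	15400000
18	q	19000000	78077248
19	p	1	24400000
19	q	28600000	59128983
20	p	1	25600000
20	q	29400000	63025520
21	p	1	10900000
21	q	14300000	48129895
22	p	1	12200000
22	q	17900000	51304566
X	p	1	58600000
X	q	61700000	155270560
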