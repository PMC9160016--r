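140	3	0
280	8	1
360	4	2
380	3	8
540	1	10
580	9	8
620	2	5
660	11	7
700	7	10
820	9	3
840	0	7
900	0	1
920	0	2
920	1	4
940	1	2
940	7	1
960	2	9
1000	7	0
1000	6	5
1200	0	1
1200	3	4
1200	9	7
1220	0	2
1220	3	5
1240	1	2
1240	4	5
1280	5	9
1500	0	1
1500	3	4
1520	0	2
1520	3	5
1540	1	2
1540	4	5
1580	3	4
1640	8	10
1720	9	8
1760	11	2
1800	0	1
1820	0	2
1840	1	2
1860	0	6
1880	1	4
1960	1	7
2100	0	1
2120	0	2
2140	1	2
2180	5	0
2260	10	5
2260	4	11
2320	1	2
2400	0	1
2400	8	0
2420	0	2
2440	1	2
2440	0	9
2560	7	9
2560	5	9
2600	9	6
2640	6	10
2680	4	7
2700	0	1
2700	5	10
2720	0	2
2740	1	2
2800	7	4
3000	0	1
3000	3	4
3000	5	9
3020	0	2
3020	3	5
3020	5	6
3040	1	2
3040	4	5
3140	5	11
3140	3	11
3160	5	1
3180	1	11
3300	0	1
3320	0	2
3340	1	2
3380	11	8
3400	1	9
3480	1	11
3600	0	1
3600	3	4
3620	0	2
3620	3	5
3640	1	2
3640	4	5
3800	0	9
3840	9	5
3880	2	4
3880	11	2
3900	10	3
4060	10	3
4100	0	3
4200	0	1
4200	3	4
4220	0	2
4220	3	5
4220	3	0
4240	1	2
4240	4	5
4420	11	0
4500	0	1
4520	0	2
4540	1	2
4540	4	0
4760	2	11
4800	0	1
4820	0	2
4820	5	8
4840	1	2
4840	7	6
4880	6	8
5080	9	8
5100	0	1
5100	3	4
5120	0	2
5120	3	5
5140	1	2
5140	4	5
5160	5	8
5200	3	5
5200	8	10
5220	7	5
5280	8	0
5420	4	5
5420	4	0
5520	10	0
5580	1	10
5580	8	11
5700	0	1
5720	0	2
5720	6	4
5740	1	2
5860	10	3
5880	0	5
6000	0	1
6000	3	4
6020	0	2
6020	3	5
6040	1	2
6040	4	5
6040	9	6
6160	8	9
6300	0	1
6320	0	2
6340	1	2
6340	0	1
6380	10	7
6420	3	11
6480	10	6
6520	5	9
6560	9	4
6660	1	3
6660	1	4
6680	2	7
6780	10	5
6800	10	7
6900	0	1
6900	3	4
6920	0	2
6920	3	5
6940	1	2
6940	4	5
7020	0	6
7080	5	4
7140	3	11
7160	5	1
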