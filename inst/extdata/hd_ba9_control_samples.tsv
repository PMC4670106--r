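# columns: sample_id pmi age_of_death rin reads
sample_id	pmi	age_of_death	rin	reads
C_0012	19	66	7.1	118327116
C_0013	15	69	7.8	89478160
C_0014	21	79	8.0	65377604
C_0015	10	61	8.2	123746070
C_0016	20	58	8.4	67758208
C_0017	21	70	8.2	72238818
C_0018	17	66	8.5	64688322
C_0020	24	60	7.9	83696384
C_0021	26	76	7.3	79487172
C_0022	17	61	7.8	73133936
C_0023	18	62	6.6	94493436
C_0024	26	69	8.7	62989822
C_0025	25	61	8.1	55810684
C_0026	11	88	7.1	72581752
C_0029	13	93	6.4	59386108
C_0031	24	53	7.3	73283170
C_0032	24	57	8.3	70994352
C_0033	15	43	7.5	69505712
C_0034	14	71	7.8	65979612
C_0035	21	46	7.6	62300754
C_0036	17	40	7.5	63961372
C_0037	28	44	8.3	60288132
C_0038	20	57	7.7	61019098
C_0039	15	80	7.3	74892650
C_0050	2	74	8.5	85310070
C_0053	2	69	8.4	167044880
C_0060	2	76	7.5	103952680
C_0061	3	78	7.6	95393100
C_0062	2	87	8.7	83773400
C_0065	2	86	8.7	115714502
C_0069	24	54	8.3	128459102
C_0070	19	68	6.3	145087692
C_0071	21	106	7.6	86840836
C_0075	23	52	7.4	99946984
C_0076	30	46	8.2	85890116
C_0077	21	36	8.5	80103722
C_0081	26	55	7.6	82917984
C_0082	18	57	7.8	123118398
C_0083	32	66	8.4	80696360
C_0087	19	64	8.7	77198978
C_0002	2	73	7.7	120108434
C_0003	2	91	7.9	38420004
C_0004	2	82	8.6	75850406
C_0005	2	97	9.1	150661916
C_0006	5	86	8.6	63607838
C_0008	2	91	8.7	66131458
C_0009	3	81	6.0	69284092
C_0010	2	79	8.4	60542776
C_0011	2	63	6.5	93702684
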