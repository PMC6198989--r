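sample	rs0638346	rs2003314	rs8758910	rs8777064
S01	0	1	0	2
S02	0	0	0	1
S03	0	0	1	1
S04	0	1	0	2
S05	0	0	0	1
S06	0	1	0	2
S07	0	0	0	0
S08	0	0	0	1
S09	0	0	0	1
S10	2	0	2	0
S11	0	0	0	1
S12	0	0	0	1
S13	1	0	1	0
S14	0	0	0	0
S15	0	0	1	1
S16	0	0	1	0
S17	0	0	0	1
S18	0	0	0	1
S19	0	1	0	1
S20	0	0	0	1
S21	0	0	1	1
S22	1	0	1	0
S23	0	0	1	0
S24	1	1	1	0
S25	0	0	1	0
S26	1	0	2	0
S27	0	0	0	2
S28	1	1	1	0
S29	1	1	2	0
S30	0	0	0	2
S31	1	0	1	0
S32	0	0	0	2
S33	0	0	1	0
S34	0	1	0	2
S35	1	2	1	1
S36	0	1	0	1
S37	1	1	1	0
S38	0	0	1	1
S39	0	1	0	2
S40	0	1	0	2
S41	1	1	1	0
S42	0	1	1	1
S43	0	0	1	0
S44	1	0	1	0
S45	0	1	0	2
S46	0	0	0	1
S47	0	0	0	1
S48	0	0	0	0
S49	0	1	0	1
S50	1	0	1	0
S51	0	1	0	1
S52	0	0	0	0
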