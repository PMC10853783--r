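species	rank	id	sequence
rabbit	1	130	CCGAUGU
rabbit	2	122	UGCAUGC
rabbit	3	159	UGUAUGC
rabbit	4	160	UGUAUGU
rabbit	5	157	UGGAUGC
rabbit	6	42	UUAAUGC
rabbit	7	107	UUCAUGU
rabbit	8	23	CCAAUGU
rabbit	9	74	UACAUGC
rabbit	10	55	CGAAUGU
rabbit	11	91	UCCAUGU
rabbit	12	87	CCCAUGU
fruit_fly	1	157	UGGAUGC
fruit_fly	2	131	CCUAUGC
fruit_fly	3	160	UGUAUGU
fruit_fly	4	107	UUCAUGU
fruit_fly	5	122	UGCAUGC
fruit_fly	6	42	UUAAUGC
fruit_fly	7	159	UGUAUGC
fruit_fly	8	23	CCAAUGU
fruit_fly	9	55	CGAAUGU
fruit_fly	10	74	UACAUGC
fruit_fly	11	91	UCCAUGU
fruit_fly	12	87	CCCAUGU
wheat	1	86	CCCAUGC
wheat	2	160	UGUAUGU
wheat	3	137	CAGAUGC
wheat	4	22	CCAAUGC
wheat	5	130	CCGAUGU
wheat	6	107	UUCAUGU
wheat	7	42	UUAAUGC
wheat	8	74	UACAUGC
wheat	9	23	CCAAUGU
wheat	10	91	UCCAUGU
wheat	11	55	CGAAUGU
wheat	12	87	CCCAUGU
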