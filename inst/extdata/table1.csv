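rank,code,efficiency,kcat,flux,force_rt,dissipation_rt,generalist
1,CAII,83600000,805433,421874,1.81,125000,FALSE
2,KSI,302000000,35031,13756,8.43,115900,FALSE
3,CAII-T200H,67700000,209682,33593,1.87,62920,FALSE
4,CAI,24810000,77746,15691,1.81,28370,FALSE
5,Lac1,26030200,1905,1757,8.27,14526,FALSE
6,RTEM,23513000,975,873,7.74,6757,FALSE
7,sgPPase,70427239,812,625,9.95,6214,FALSE
8,GPI,21721831,1550,855,3.42,2928,TRUE
9,GAL,1918000,730,152,7.6,1154,FALSE
10,coliMgPPase,44481928,147,128,8.71,1116,FALSE
11,yeastPPase,29765749,189,122,7.74,946,FALSE
12,MR,1080105,632,317,2.52,798,FALSE
13,PC1,10100000,60.8,60.6,11.37,689,FALSE
14,FH,6355555,1833,508,1.35,687,FALSE
15,KSI-D38E,2769512,129,73,8.97,655,FALSE
16,KIN,2225553,106,41.4,13.73,569,FALSE
17,RPE,1605047,305,191,2.91,554,FALSE
18,dPGM,1650000,330,179,2.37,423,FALSE
19,PMI,595000,800,161,2.27,365,FALSE
20,AROH,589474,50.4,12.8,22.59,289,FALSE
21,CypC,471129,115,99.6,2.71,270,FALSE
22,ALF,5086315,52.6,51.8,5.14,266,FALSE
23,CypB,379186,103,90.1,2.73,246,FALSE
24,EpiI,100400,502,92.6,2.65,245,FALSE
25,TPI,542518,714,209,1.16,242,FALSE
26,ALS,3255879,40.2,39.4,6.05,239,FALSE
27,CypA,936569,97.3,87.0,2.73,238,FALSE
28,AR,172197,1692,827,1.80,229,FALSE
29,yPGM,747211,380,93.4,1.03,96.2,FALSE
30,GeoCyp,847000,36.85,33.75,2.73,92.19,FALSE
31,ALaO,295908,6.8,6.58,9.83,64.72,FALSE
32,EpiT,10333,341,28,1.03,28.9,FALSE
33,NSAAR,2857,20,10.1,2.34,23.67,FALSE
34,iPGM,104762,22,8.75,2.32,20.29,FALSE
35,ALiO,8890,1.602,1.276,10.01,12.77,FALSE
36,API,50333,100,10.7,1.08,11.58,FALSE
37,RPI,15143,33.3,5.16,2.12,10.93,FALSE
38,RacE2mut,14081,81.67,4.36,2.24,9.76,FALSE
39,TIProRC,1996,12.13,1.64,3.54,5.82,TRUE
40,LYSROEN,318,3.5,2.39,2.4,5.73,FALSE
41,TIProR,2300,2.783,1.989,2.26,4.485,TRUE
42,KYNase_66,34526,0.74,0.602,7.03,4.233,FALSE
43,RacE2,5311,32.4,1.39,2.84,3.958,FALSE
44,ATAmut2,1427,1.87,0.986,2.07,2.037,FALSE
45,KYNase_93D9,38565,0.67,0.424,4.77,2.022,TRUE
46,ATAmut1,4875,1.95,1.123,1.59,1.785,FALSE
47,TM0831,17.9,2.156,0.244,2.53,0.618,TRUE
48,ATA,217,0.5,0.216,2.06,0.444,FALSE
49,FAProR,18.9,0.597,0.164,1.32,0.216,TRUE
50,HcmABwt,481,0.05,0.048,3.43,0.163,FALSE
51,SerR,31,0.31,0.056,2.62,0.148,FALSE
52,TAM,37.8,0.0209,0.0135,8.47,0.114,FALSE
53,HcmAmut,10.9,0.02,0.0165,4.05,0.0666,FALSE
54,NSAARN,3.89,0.07,0.023,2.86,0.0659,FALSE
55,EpiTmut,15.9,4.9,0.0474,0.94,0.044,FALSE
56,GI,0.0365,0.029,0.0097,2.36,0.023,TRUE
57,HcmIcm,1.8182,0.001,0.00094,5.21,0.0049,FALSE
58,GI3,0.00018,0.00012,0.000015,2.96,0.000044,TRUE
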