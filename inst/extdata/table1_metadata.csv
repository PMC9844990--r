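experiment_id,lab,injection_age,perfusion_age,muscle,titre_IU_per_ml,n_starter_mn,n_double_mn,ipsi_dorsal_median_um,n_premotor_ipsi,n_premotor_contra,n_premotor,in_mn_ratio,sampling
170427 n2,UCL,2,11,LG,1e10,46,3,285,741,116,857,19,1/2 (30 um)
170427 n2,UCL,2,11,TA,5e9,41,,298,912,88,1000,24,1/2 (30 um)
170427 n3,UCL,2,11,LG,1e10,32,2,267,620,87,707,22,1/2 (30 um)
170427 n3,UCL,2,11,TA,5e9,6,,276,386,34,420,70,1/2 (30 um)
170503 n6,UCL,2,11,LG,1e10,83,1,294,1935,639,2574,31,1/2 (30 um)
170503 n6,UCL,2,11,TA,5e9,55,,315,1887,315,2202,40,1/2 (30 um)
170125 n3,UCL,1,10,LG,5e9,39,0,365,670,107,777,20,1/2 (30 um)
170125 n3,UCL,1,10,MG,5e9,39,,353,819,307,1126,29,1/2 (30 um)
170508 n7,UCL,2,11,LG,1e10,110,3,352,1955,382,2337,21,1/2 (30 um)
170508 n7,UCL,2,11,MG,5e9,67,,322,1497,429,1926,29,1/2 (30 um)
170125 n7,UCL,1,10,TA,5e9,47,0,363,907,308,1215,26,1/2 (30 um)
170125 n7,UCL,1,10,PL,5e9,39,,380,1044,195,1239,32,1/2 (30 um)
170125 n8,UCL,1,10,TA,5e9,22,2,343,920,157,1077,49,1/2 (30 um)
170125 n8,UCL,1,10,PL,5e9,22,,330,741,83,824,37,1/2 (30 um)
1570,UoG,1,10,LG,2e8,11,-,322,1111,404,1515,138,1/8 (60 um)
1571,UoG,1,10,LG,2e8,12,-,340,760,196,956,80,1/8 (60 um)
1573,UoG,1,10,TA,5e8,10,-,332,447,68,515,52,1/8 (60 um)
1574,UoG,1,10,TA,5e8,14,-,365,297,26,323,23,1/8 (60 um)
1577,UoG,2,10,LG,2e9,18,2,329,313,43,356,20,1/8 (60 um)
1577,UoG,2,10,TA,5e9,26,,312,688,105,793,31,1/8 (60 um)
1578,UoG,2,10,LG,2e9,21,5,330,292,34,326,16,1/8 (60 um)
1578,UoG,2,10,TA,5e9,22,,346,790,130,920,42,1/8 (60 um)
1579,UoG,2,10,LG,2e9,30,1,322,1023,194,1217,41,1/8 (60 um)
1579,UoG,2,10,MG,5e8,7,,306,169,19,188,27,1/8 (60 um)
1580,UoG,2,10,LG,2e9,14,0,316,414,48,462,33,1/8 (60 um)
1580,UoG,2,10,MG,5e8,8,,348,470,87,557,70,1/8 (60 um)
1605,UoG,1,10,MG,1e8,6,-,340,412,110,522,87,1/8 (60 um)
1611,UoG,1,10,PL,1e8,2,-,328,167,24,191,96,1/8 (60 um)
1613,UoG,2,10,PL,1e8,1,-,340,164,16,180,180,1/8 (60 um)
1639,UoG,2,10,TA,2e8,15,-,341,591,94,685,46,1/8 (60 um)
1640,UoG,2,10,PL,2e8,20,-,322,629,122,751,38,1/8 (60 um)
1644,UoG,2,10,LG,1e8,1,-,344,142,32,174,174,1/8 (60 um)
1644,UoG,2,10,TA,2e8,-,,296,57,11,68,-,1/8 (60 um)
1646,UoG,2,10,LG,1e8,1,-,261,90,16,106,106,1/8 (60 um)
1646,UoG,2,10,TA,2e8,3,,305,76,13,89,30,1/8 (60 um)
1653,UoG,2,10,LG,1e8,2,-,307,60,6,66,33,1/8 (60 um)
1653,UoG,2,10,TA,2e8,2,,312,58,8,66,33,1/8 (60 um)
1656,UoG,2,10,LG,1e8,-,-,311,563,145,708,-,1/8 (60 um)
1657,UoG,2,10,LG,1e8,1,-,321,323,51,374,374,1/8 (60 um)
1660,UoG,2,10,MG,2e8,7,-,324,509,3,512,73,1/8 (60 um)
1661,UoG,2,10,MG,2e8,10,-,338,175,63,238,24,1/8 (60 um)
1662,UoG,2,10,MG,2e8,10,-,313,375,230,605,61,1/8 (60 um)
1701,UoG,2,10,LG,2e9,8,2,351,169,26,195,24,1/8 (60 um)
1701,UoG,2,10,MG,5e9,34,,329,594,190,784,23,1/8 (60 um)
1702,UoG,2,10,LG,2e9,14,2,331,561,107,668,48,1/8 (60 um)
1702,UoG,2,10,MG,5e9,2,,322,76,11,87,44,1/8 (60 um)
353,MDC,4,10,GS,1e9,31,-,283,1542,431,1973,64,All (40 um)
399,MDC,4,10,GS,1e9,41,-,286,569,77,646,16,All (40 um)
1332,MDC,4,10,GS,1e9,18,-,317,1605,323,1928,107,All (40 um)
1349,MDC,4,10,GS,1e9,18,-,305,1416,459,1875,104,All (40 um)
700,MDC,4,10,TA,1e9,47,-,318,1723,122,1845,39,All (40 um)
721,MDC,4,10,TA,1e9,22,-,310,1934,465,2399,109,All (40 um)
1324,MDC,4,10,TA,1e9,17,-,292,2041,301,2342,138,All (40 um)
1,Salk,2,10,GS,1e11,N/A,N/A,328,9185,2735,11920,N/A,All (60 um)
1,Salk,2,10,TA,1e11,N/A,N/A,349,3330,731,4061,N/A,All (60 um)
2,Salk,2,10,GS,1e11,N/A,N/A,303,8827,3867,12694,N/A,All (60 um)
2,Salk,2,10,TA,1e11,N/A,N/A,294,3198,1132,4330,N/A,All (60 um)
a,Salk,1,8,GS,1e10,N/A,N/A,248,334,42,376,N/A,1/9 (30 um)
b,Salk,1,8,GS,1e10,N/A,N/A,237,275,30,305,N/A,1/9 (30 um)
22 a_4,Salk,2,9,GS,3e11,N/A,N/A,403,464,58,522,N/A,All (60 um)
26 a_1,Salk,2,9,GS,3e11,N/A,N/A,383,941,91,1032,N/A,All (60 um)
26 a_2,Salk,2,9,GS,3e11,N/A,N/A,351,1910,401,2311,N/A,All (60 um)
26 a_4,Salk,2,9,GS,3e11,N/A,N/A,382,1923,392,2315,N/A,All (60 um)
26_1,Salk,2,9,TA,3e11,N/A,N/A,348,3236,263,3499,N/A,All (60 um)
26_3,Salk,2,9,TA,3e11,N/A,N/A,367,2078,465,2543,N/A,All (60 um)
26_4,Salk,2,9,TA,3e11,N/A,N/A,350,2494,597,3091,N/A,All (60 um)
1_1PRV,Salk,11,13,GS,1e9,N/A,N/A,318,430,54,484,N/A,1/4 (60 um)
1_1PRV,Salk,11,13,TA,1e9,N/A,N/A,,,,,N/A,1/4 (60 um)
1_4PRV,Salk,11,13,GS,1e9,N/A,N/A,349,238,23,261,N/A,1/4 (60 um)
1_4PRV,Salk,11,13,TA,1e9,N/A,N/A,,,,,N/A,1/4 (60 um)
2_2PRV,Salk,11,13,GS,1e9,N/A,N/A,357,515,82,597,N/A,1/4 (60 um)
2_2PRV,Salk,11,13,TA,1e9,N/A,N/A,,,,,N/A,1/4 (60 um)
3_3PRV,Salk,11,13,GS,1e9,N/A,N/A,377,1005,53,1058,N/A,1/4 (60 um)
3_3PRV,Salk,11,13,TA,1e9,N/A,N/A,,,,,N/A,1/4 (60 um)
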