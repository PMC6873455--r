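procedure,payment,q1,q2,q3,q4,q5,printed_abs_diff,printed_pct_diff,abs_reconciles
PHR,total_price_std,14228,15796,16989,18706,28613,14385,101,1
PHR,total_casemix,15039,16042,17049,18486,26216,11177,74,1
PKR,total_price_std,15562,16851,18151,19718,29512,13950,90,1
PKR,total_casemix,16046,17111,18157,19559,28037,11990,75,0
CABG,total_price_std,33205,38170,43085,49830,68076,34870,105,0
CABG,total_casemix,35801,39256,42980,47518,59360,23558,66,0
LSF,total_price_std,26253,29777,32641,35928,49961,23707,90,0
LSF,total_casemix,27271,30337,32694,35256,47210,19939,73,1
colectomy,total_price_std,18458,23940,27761,33850,46939,28480,154,0
colectomy,total_casemix,23152,25726,28340,31670,37994,14842,64,1
colectomy,index_hospitalization,13466,15591,17509,20067,27141,13674,NA,0
colectomy,readmissions,1626,9949,10892,12722,18883,17257,NA,1
colectomy,professional_fees,5019,5457,5814,6371,7320,2301,46,1
colectomy,post_acute,1179,1370,1539,1750,2194,1014,NA,0
PKR,index_hospitalization,10568,11434,12172,13393,21893,11324,107,0
PKR,readmissions,0,8449,9645,10818,14278,14278,NA,1
PKR,professional_fees,3830,4259,4521,4762,5306,1475,NA,0
PKR,post_acute,840,952,986,1031,1138,298,NA,1
PHR,index_hospitalization,10588,11403,12165,13324,21611,11022,NA,0
PHR,readmissions,0,10793,11528,12262,13885,13885,NA,1
PHR,professional_fees,3303,3494,3597,3767,4026,722,22,0
PHR,post_acute,534,593,625,656,732,197,NA,0
LSF,index_hospitalization,18872,21506,22994,25793,37705,18833,NA,1
LSF,readmissions,0,6970,8507,10082,14607,14607,NA,1
LSF,professional_fees,6463,7343,7882,8418,9746,3282,NA,0
LSF,post_acute,421,550,629,743,974,553,NA,1
CABG,index_hospitalization,26339,28848,32877,36945,48867,22527,NA,0
CABG,readmissions,0,7175,8827,9946,13289,13289,NA,1
CABG,professional_fees,5877,6596,7088,7714,8571,2693,46,0
CABG,post_acute,1110,1298,1433,1615,2129,1019,NA,1
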