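bodyId,type,label,subphase
2068801704,s-LNv,s-LNv1,M
1664980698,s-LNv,s-LNv2,M
2007068523,s-LNv,s-LNv3,M
1975347348,s-LNv,s-LNv4,M
5813056917,LNd,LNd4,E1
5813021192,LNd,LNd5,E1
5813069648,LNd,LNd6,E2
511051477,5th LNv,5th LNv,E2
296544364,LNd,LNd1,E3
448260940,LNd,LNd2,E3
5813064789,LNd,LNd3,E3
356818551,LPN,LPN1,
480029788,LPN,LPN2,
450034902,LPN,LPN3,
546977514,LPN,LPN4,
264083994,DN1a,DN1a1,
5813022274,DN1a,DN1a2,
5813010153,DN1pA,DN1pA1,
324846570,DN1pA,DN1pA2,
325529237,DN1pA,DN1pA3,
387944118,DN1pA,DN1pA4,
387166379,DN1pA,DN1pA5,
386834269,DN1pB,DN1pB1,
5813071319,DN1pB,DN1pB2,
1884625521,l-LNv,lLNv1,
2065745704,l-LNv,lLNv2,
5813001741,l-LNv,lLNv3,
5813026773,l-LNv,lLNv4,
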