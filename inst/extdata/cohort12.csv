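id,pjk,weight_kg,age_years,gender,reported_risk,pre_pja_deg,post_pja_deg,reported_optimal_pja_deg
1,0,56,15,M,0.425,12.4,12.9,12.6
2,0,42,17,F,0.296,5.8,7.7,6.3
3,0,64,13,F,0.345,6.9,7.8,7.4
4,0,52,20,M,0.174,5.2,9.6,3.9
5,0,37,13,F,0.270,2.4,1.7,3.4
6,0,45,16,M,0.331,18.0,16.6,18.2
7,0,71,20,F,0.556,0.9,4.8,1.2
8,0,41,13,F,0.306,4.6,3.2,6.0
9,0,40,13,F,0.361,5.1,7.6,6.1
10,1,32.5,16,M,0.508,10.7,17.2,11.5
11,1,60,18,F,0.401,4.1,12.4,5.5
12,1,47.5,18,F,0.586,9.4,9.3,9.5
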