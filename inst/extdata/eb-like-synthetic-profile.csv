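z_star,Aa_m2,gamma_m
0.14,0.00071,2.22
0.15825,0.000727482556354904,2.27466376775759
0.1765,0.000779499746860882,2.43730906764952
0.19475,0.000864770735652518,2.70393103260365
0.213,0.000981195867987575,3.06796454497523
0.23125,0.0011259083707151,3.52044589153173
0.2495,0.00129534494174469,4.05023347982142
0.26775,0.00148533349036984,4.64428218115641
0.286,0.00169119586798758,5.28796454497523
0.30425,0.00190786305964287,5.96543097522138
0.3225,0.00213,6.66
0.34075,0.00235213694035713,7.35456902477862
0.359,0.00256880413201243,8.03203545502477
0.37725,0.00277466650963016,8.67571781884359
0.3955,0.00296465505825531,9.26976652017858
0.41375,0.0031340916292849,9.79955410846827
0.432,0.00327880413201243,10.2520354550248
0.45025,0.00339522926434748,10.6160689673964
0.4685,0.00348050025313912,10.8826909323505
0.48675,0.0035325174436451,11.0453362322424
0.505,0.00355,11.1
0.52325,0.0035325174436451,11.0453362322424
0.5415,0.00348050025313912,10.8826909323505
0.55975,0.00339522926434748,10.6160689673964
0.578,0.00327880413201243,10.2520354550248
0.59625,0.0031340916292849,9.79955410846827
0.6145,0.00296465505825531,9.26976652017858
0.63275,0.00277466650963016,8.67571781884359
0.651,0.00256880413201243,8.03203545502477
0.66925,0.00235213694035713,7.35456902477863
0.6875,0.00213,6.66
0.70575,0.00190786305964287,5.96543097522138
0.724,0.00169119586798758,5.28796454497523
0.74225,0.00148533349036984,4.64428218115641
0.7605,0.00129534494174469,4.05023347982142
0.77875,0.0011259083707151,3.52044589153173
0.797,0.000981195867987576,3.06796454497524
0.81525,0.000864770735652518,2.70393103260365
0.8335,0.000779499746860882,2.43730906764952
0.85175,0.000727482556354905,2.27466376775759
0.87,0.00071,2.22
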