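age_years,n_total,n_measured_1y,pct_1y_printed,n_measured_4y,pct_4y_printed,scheduled_visit
0,5570,5387,96.7,5387,96.7,1
1,5953,5780,97.1,5839,98.1,1
2,5940,5624,94.7,5898,99.3,1
3,5874,4996,85.1,5836,99.4,1
4,6411,4992,77.9,6307,98.4,1
5,6541,1231,18.8,6342,97.0,0
6,6564,5119,78.0,6332,96.5,1
7,6593,1323,20.1,6239,94.6,0
8,6822,4999,73.3,6415,94.0,1
9,6605,1728,26.2,6125,92.7,0
10,6717,1923,28.6,5979,89.0,0
11,6397,3719,58.1,5808,90.8,1
12,6518,1978,30.4,5684,87.2,0
13,6588,1147,17.4,5629,85.4,0
14,6228,3628,58.3,5243,84.2,1
total,95321,53574,56.2,89063,93.4,
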