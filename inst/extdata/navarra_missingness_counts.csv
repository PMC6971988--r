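age_group,variable,level,n_total,n_measured,n_not_measured,odds_ratio,ci_low,ci_high,reference
6-9,sex,boy,5498,5203,295,1,,,1
6-9,sex,girl,5313,5075,238,1.18,0.99,1.42,0
6-9,status_base,underweight,78,70,8,0.52,0.25,1.11,0
6-9,status_base,normal,7628,7241,387,1,,,1
6-9,status_base,at_risk_overweight,2291,2198,93,1.29,1.02,1.63,0
6-9,status_base,overweight_obese,814,769,45,0.99,0.72,1.37,0
6-9,income,basic,510,442,68,0.40,0.31,0.54,0
6-9,income,lt_18k,4657,4390,267,1,,,1
6-9,income,18k_to_100k,5546,5352,194,1.70,1.41,2.06,0
6-9,income,ge_100k,97,93,4,1.45,0.53,3.98,0
6-9,residence,rural,6447,6159,288,1,,,1
6-9,residence,urban,4364,4119,245,0.79,0.66,0.94,0
10-14,sex,boy,5498,4849,649,1,,,1
10-14,sex,girl,5313,4761,552,1.15,1.02,1.29,0
10-14,status_base,underweight,78,62,16,0.53,0.30,0.92,0
10-14,status_base,normal,7628,6763,865,1,,,1
10-14,status_base,at_risk_overweight,2291,2057,234,1.14,0.97,1.32,0
10-14,status_base,overweight_obese,814,728,86,1.13,0.90,1.44,0
10-14,income,basic,510,409,101,0.57,0.45,0.72,0
10-14,income,lt_18k,4657,4085,572,1,,,1
10-14,income,18k_to_100k,5546,5035,511,1.38,1.22,1.57,0
10-14,income,ge_100k,97,80,17,0.66,0.39,1.12,0
10-14,residence,rural,6447,5735,712,1,,,1
10-14,residence,urban,4364,3875,489,0.99,0.87,1.12,0
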