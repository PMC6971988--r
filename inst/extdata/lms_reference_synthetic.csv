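sex,age_months,L,M,S
boy,72,-1.2,15.8,0.085
boy,96,-1.6,16.2,0.095
boy,120,-1.9,16.9,0.110
boy,144,-2.1,17.9,0.120
boy,168,-2.0,19.1,0.125
girl,72,-1.1,15.6,0.090
girl,96,-1.5,16.0,0.100
girl,120,-1.8,16.9,0.115
girl,144,-1.9,18.1,0.125
girl,168,-1.8,19.4,0.128
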