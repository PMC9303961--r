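# Synthetic stand-in for a 1985-style Japanese standard population
# (thousands). The age structure is plausible but NOT the official table;
# replace this file with the official weights for real analyses. All
# package computations are weight-agnostic.
age_band,population
0-4,7600
5-9,8700
10-14,10100
15-19,8900
20-24,8100
25-29,7700
30-34,8800
35-39,10600
40-44,9100
45-49,8500
50-54,7600
55-59,6600
60-64,5200
65-69,4100
70-74,3400
75-79,2500
80-84,1600
85+,1000
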