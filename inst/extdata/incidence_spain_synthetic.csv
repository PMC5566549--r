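# Synthetic age-specific prostate-cancer incidence table (per 100,000
# person-years) with the shape of registry-published Spanish rates circa
# 2012.  Illustrative values for examples and tests, not registry data.
age_low,age_high,rate_per_100k
40,44,2.1
45,49,9.8
50,54,38.5
55,59,102.0
60,64,208.0
65,69,330.0
70,74,402.0
75,79,381.0
80,84,349.0
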