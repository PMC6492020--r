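"psi_mpa","plc_pct"
-0.0555,0
-3.0113,49.819
-4.4215,82.777
-4.6513,84.928
-3.7813,82.949
-1.0399,5.811
-3.2997,67.595
-0.1397,0
-4.1707,78.914
-2.7045,50.232
-4.1413,86.8
-3.8426,81.383
-1.1359,14.914
-4.5185,84.741
-2.7328,54.584
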