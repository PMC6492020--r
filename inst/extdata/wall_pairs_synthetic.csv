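"t_um","b_um","pair_mean_d_um","sample_id"
10.97,26.404,25.38,"plant1"
10.742,26.56,26.14,"plant1"
8.831,22.003,22.44,"plant1"
10.034,25.813,26.64,"plant1"
9.896,24.492,24.68,"plant1"
8.281,23.634,22.83,"plant1"
9.625,25.156,23.93,"plant1"
7.732,20.943,19.7,"plant1"
10.741,24.599,24.01,"plant1"
10.704,24.935,25.44,"plant2"
8.931,23.204,21.7,"plant2"
9.592,25.034,24.16,"plant2"
9.619,26.543,27.84,"plant2"
8.679,21.788,23.06,"plant2"
9.169,23.236,23.94,"plant2"
9.214,26.58,26.08,"plant2"
10.07,26.848,26.89,"plant2"
9.224,20.822,21.55,"plant2"
8.841,23.325,23.68,"plant3"
8.339,23.922,24.3,"plant3"
10.622,26.328,25.48,"plant3"
7.413,20.971,20.12,"plant3"
9.237,26.922,26.59,"plant3"
9.917,26.627,27.95,"plant3"
8.062,20.577,21.96,"plant3"
8.605,23.599,24.32,"plant3"
6.712,22.731,23.43,"plant3"
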