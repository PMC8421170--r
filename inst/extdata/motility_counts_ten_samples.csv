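sample,immotile,fast,fast_mean_velocity,fast_sd,slow,slow_mean_velocity,slow_sd,reported_class
1,51,4,34.5,1.3,7,23.2,4.6,abnormal
2,19,4,49.5,1.2,5,13.6,7.1,abnormal
3,12,14,36.9,3.9,7,12.8,4.5,normal
4,16,10,36.6,4.5,9,4.5,3.05,normal
5,29,4,27.5,2,12,6.34,4.22,abnormal
6,16,3,25.9,0.77,6,5.4,2.3,abnormal
7,19,3,26.2,0.7,3,17.4,2.62,abnormal
8,15,4,26.2,0.78,6,8.8,5.4,normal
9,12,4,29.5,4.5,7,4.1,2.54,normal
10,16,5,27.5,2,2,3.85,1.48,abnormal
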