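sample,motile,immotile,method,accuracy,sensitivity,specificity
1,11,51,proposed,91.0,90.0,100
2,9,19,proposed,98.0,97.0,97.0
3,21,12,proposed,91.3,95.0,98.0
4,19,16,proposed,95.0,98.3,66.0
5,16,29,proposed,94.4,93.0,96.7
6,9,16,proposed,90.0,90.0,50.0
7,6,19,proposed,91.2,100,50.0
8,10,15,proposed,91.7,100,50.0
9,11,12,proposed,92.8,100,66.6
10,7,16,proposed,87.5,100,50.0
1,11,51,adaptive,81.3,75.0,81.0
2,9,19,adaptive,77.8,86.4,79.2
3,21,12,adaptive,84.6,90.5,80.6
4,19,16,adaptive,67.5,81.0,72.0
5,16,29,adaptive,73.8,75.0,72.7
6,9,16,adaptive,65.7,75.0,60.9
7,6,19,adaptive,53.8,42.9,60.0
8,10,15,adaptive,65.4,58.8,72.2
9,11,12,adaptive,65.7,58.8,72.6
10,7,16,adaptive,55.2,58.3,52.9
1,11,51,global,40.0,33.3,46.2
2,9,19,global,41.2,22.2,62.5
3,21,12,global,25.8,40.0,40.0
4,19,16,global,25.0,37.5,20.0
5,16,29,global,28.1,18.2,33.3
6,9,16,global,50.0,60.0,45.5
7,6,19,global,30.8,33.3,30.0
8,10,15,global,37.5,50.0,30.2
9,11,12,global,52.2,50.0,53.3
10,7,16,global,38.9,25.0,50.0
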