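subject,left_vs_stop,right_vs_stop,forward_vs_stop,back_vs_stop
1,98.4,98.7,81.1,86.5
2,99.8,99.2,79.1,84.1
3,93.2,94.7,81.2,85.4
4,97.7,96.5,80.1,80.8
5,98.1,88.2,81.2,86.9
6,91.1,99.5,84.2,86.6
7,99.2,98.1,77.2,81.1
8,98.0,98.2,83.1,87.1
9,91.2,90.4,80.2,83.1
10,85.0,84.1,74.1,76.3
11,94.5,95.2,82.8,86.1
12,90.1,94.0,78.2,79.3
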