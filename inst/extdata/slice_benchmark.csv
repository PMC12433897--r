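object,long_actual,short_actual,long_pred,short_pred,area_pred,long_error,short_error,long_acc,short_acc
1,17.0,15.6,17.4,16.0,215.3,2.4,2.6,97.6,97.4
2,16.2,15.4,17.1,15.7,204.8,5.6,1.9,94.4,98.1
3,14.2,13.6,15,13.8,157.8,5.6,1.5,94.4,98.5
4,19.6,14.7,20.7,16.3,266.8,5.6,10.9,94.3,89.1
5,19.2,18.3,19.6,18.2,275.7,2.1,0.5,97.9,99.5
6,18.8,16.8,19.8,17.3,262.3,5.3,3.0,94.7,97.0
7,23.3,15.2,23.5,15.3,284.6,0.9,0.7,99.1,99.3
8,19.9,15.1,20.2,15.3,239.7,1.5,1.3,98.5,98.7
9,21.8,18.7,23.8,19.4,362.7,9.2,3.7,90.8,96.3
10,20.0,14.6,20.4,15.7,242.9,2.0,7.5,98.0,92.5
11,19.6,16.9,20.4,17.2,274.2,4.1,1.8,95.9,98.2
12,18.7,17.3,20.4,17.0,272.3,9.1,1.7,90.9,98.3
13,16.5,14.2,17,14.9,195.2,3.0,4.9,97.0,95.1
14,18.1,15.1,19.4,15.9,239.1,7.2,5.3,92.8,94.7
15,17.4,14.2,18.2,15.7,221.8,4.6,10.6,95.4,89.4
16,21.5,15.8,21.7,13.2,265.5,0.9,16.5,99.0,83.5
17,19.4,15.4,19.6,15.8,244.6,1.0,2.6,99.0,97.4
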