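a,session,f
1.1,1,0.039
1.1,2,0.023
1.1,3,0.005
1.1,4,0.029
1.1,5,0.015
1.1,6,0.052
1.1,7,0.028
1.1,8,0.034
1.1,9,0.073
1.1,10,0.023
1.1,11,0.018
2,1,0.019
2,2,0.023
2,3,0.054
2,4,0.034
2,5,-0.010
2,6,0.052
2,7,0.084
2,8,0.041
2,9,-0.013
2,10,0.017
2,11,-0.005
2,12,0.028
4,1,0.033
4,2,0.005
4,3,0.029
4,4,0.041
4,5,0.008
4,6,0.042
4,7,0.069
4,8,-0.022
4,9,0.069
4,10,0.035
4,11,0.048
4,12,0.018
9,1,0.007
9,2,-0.002
9,3,0.053
9,4,0.027
9,5,0.068
9,6,-0.017
9,7,0.032
9,8,0.049
9,9,0.020
9,10,-0.022
9,11,0.018
9,12,0.032
100,1,0.047
100,2,0.004
100,3,0.024
100,4,0.051
100,5,0.027
100,6,0.031
100,7,0.017
100,8,-0.017
100,9,-0.012
100,10,0.053
100,11,-0.010
100,12,-0.005
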