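n,cl90,cl95,cl99
3,0.941,0.970,0.994
4,0.765,0.829,0.926
5,0.642,0.710,0.821
6,0.560,0.625,0.740
7,0.507,0.568,0.680
8,0.468,0.526,0.634
9,0.437,0.493,0.598
10,0.412,0.466,0.568
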