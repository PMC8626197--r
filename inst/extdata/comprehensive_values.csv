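serial,nominal,predicted,reported_error_pct
1,3.1,3.16,1.9
2,3.4,3.22,5.3
3,2.9,3.10,6.5
4,3.4,3.26,4.1
5,2.8,3.10,10.7
6,2.9,2.87,1.0
7,2.7,2.84,5.2
8,2.8,3.01,7.5
9,2.8,2.97,6.1
10,2.6,2.77,6.5
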