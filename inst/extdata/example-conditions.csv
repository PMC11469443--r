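condition_id,mean,fano
1,18.6,2.9
2,11.2,2.4
3,6.8,2.1
4,3.1,1.7
5,1.2,1.3
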