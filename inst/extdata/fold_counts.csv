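fold,train_cluster,train_non_cluster,test_cluster,test_non_cluster
0,682,572,173,141
1,681,573,174,140
2,679,575,176,138
3,682,573,173,140
4,696,559,159,154
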