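{"theta1":[-0.5284,-0.5327],"V1":[8.0705,8.7239],"Sigma1":[[0.123908060219317,0.0522],[0.0522,0.114627632137003]],"theta_full":[-0.6528,-0.5796],"V_full":[16.626,16.7495],"theta1_all":-0.5809}
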