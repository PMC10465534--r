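{"u":0.5,"k_c":1,"d_A":0.1,"d_S":1,"d_G":1,"eps":0.9,"n":1,"a_T":1,"K":10,"lam":0.02}
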