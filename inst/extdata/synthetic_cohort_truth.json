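{"beta":[24.6,0.056,-0.695,0.082,-0.641,2.56,0.029],"sigma":1,"psi":[[1,0,0],[0,0.04,0],[0,0,0.25]],"tau_gen":0.5,"family":"ald"}
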