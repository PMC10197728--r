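{"segments":[[445,480,1.67],[480,510,2],[510,560,2.5],[560,602,3.33]],"reference_nm":445}
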