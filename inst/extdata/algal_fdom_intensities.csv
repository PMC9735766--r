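sample,medium,stage,is_blank,C1,C2,C3
ARC01,WC,stationary,FALSE,0.068,0.072,0.070
ARC03,WC,stationary,FALSE,0.045,0.029,0.036
ARC05,WC,stationary,FALSE,0.140,0.024,0.047
ARC06,BBM,stationary,FALSE,0.173,0.285,0.134
ARC10,BBM,stationary,FALSE,0.303,0.129,0.144
BBM,BBM,initial,TRUE,0.005,0.002,0.008
WC,WC,initial,TRUE,0.006,0.004,0.008
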