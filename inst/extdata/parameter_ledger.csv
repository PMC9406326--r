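layer,complex_units,real_scalars
Conv1,71940,290400
Conv2,186608,285144
Conv3,725760,1492992
FullyConnected1,169600,359552
FullyConnected2,1200,1200
FullyConnected3,500,500
Output,2,2
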