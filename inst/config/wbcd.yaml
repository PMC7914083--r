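# Cytology-table schedule: identity extractor over the 9 ordinal features,
# lr 0.001, 16-row (2x8) batches, momentum 0.3, weight decay 4e-4.
preset: wbcd
lr_w: 0.001
lr_M: 0.01
momentum: 0.3
weight_decay: 0.0004
outer_iters: 50
batch_K: 2
batch_L: 8
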