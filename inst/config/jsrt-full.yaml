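# Chest-radiograph schedule: 2048x2048 inputs, full-width backbone,
# initial lr 0.01 decayed x0.1 at iterations 50 and 80, 160 iterations,
# 128-image (16x8) batches, histogram enhancement on. Running this preset
# at full scale requires GPU-class compute; it is shipped for fidelity.
preset: jsrt-full
input_size: 2048
enhance: true
margin: 1.0
mu: 0.1
lr_w: 0.01
lr_M: 0.01
momentum: 0
outer_iters: 160
batch_K: 16
batch_L: 8
lr_decay: 0.1
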