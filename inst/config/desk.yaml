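# Desk-scale defaults: 64x64 inputs, reduced-width residual backbone,
# 20 alternating iterations. Matches mt_config("desk").
preset: desk
input_size: 64
enhance: false
margin: 1.0
mu: 0.1
lr_w: 0.02
lr_M: 0.05
outer_iters: 20
inner_batches: 4
metric_steps: 5
batch_K: 2
batch_L: 8
rounds: 2
n_classes: 2
n_per_class: 50
size: 64
contrast: 1.0
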