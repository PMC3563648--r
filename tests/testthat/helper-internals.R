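# aliases for unexported helpers exercised by the unit suite
conv2d <- hemiscan:::conv2d
conv_sep <- hemiscan:::conv_sep
block_mean <- hemiscan:::block_mean
resample_matrix <- hemiscan:::resample_matrix
label_components <- hemiscan:::label_components
with_seed <- hemiscan:::with_seed
dog_taps <- hemiscan:::dog_taps
item_bbox <- hemiscan:::item_bbox
band_matrix <- hemiscan:::band_matrix
cross_axis_max <- hemiscan:::cross_axis_max
hemifield_cols <- hemiscan:::hemifield_cols
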