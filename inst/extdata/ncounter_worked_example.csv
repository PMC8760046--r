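line,venus_counts,shank2_counts,all_shanks_counts
SH-WT,11064,962,6717
SH-RX,11550,859,6630
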