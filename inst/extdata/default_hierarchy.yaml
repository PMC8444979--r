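# Default mixed-depth cell-type hierarchy: broad stromal categories sit at
# level 1; immune cells resolve into subtypes and NK activation states.
epithelial: ~
endothelial: ~
fibroblast: ~
immune:
  myeloid:
    monocyte: ~
    macrophage: ~
  lymphoid:
    nk_resting: ~
    nk_activated: ~
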