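# Balanced depth-3 hierarchy with 8 terminal cell types, used by the
# simulation benchmark: every terminal phenotype is a level-3 node, so each
# is compared against its sibling with the deepest (largest-k) marker budget.
stromal:
  vascular:
    endothelial: ~
    pericyte: ~
  connective:
    fibroblast: ~
    epithelial: ~
immune:
  myeloid:
    monocyte: ~
    macrophage: ~
  lymphoid:
    nk: ~
    t_cell: ~
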