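model	sensitivity_pct	specificity_pct
motion	81.21	90.16
fog	84.38	76.15
multistage	87.50	79.82
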