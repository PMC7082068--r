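# Combined linear + perfectly-adapting dose-response prior network.
# Six parameters: the union of the two Tyson motifs gives five named
# reactions; the sixth, basal signal-independent production of R (k_0r),
# is this package's reconstruction of the full six-parameter prior and is
# flagged as such (see the methods vignette). S is a clamped input.
species:
- S
- R
- X
reactions:
- reactants: []
  products:
    R: 1
  param: k_0r
- reactants: []
  products:
    R: 1
  param: k_srs
  modifiers:
  - S
- reactants:
    R: 1
  products: []
  param: k_r0
- reactants: []
  products:
    X: 1
  param: k_sxs
  modifiers:
  - S
- reactants:
    X: 1
  products: []
  param: k_x0
- reactants:
    R: 1
  products: []
  param: k_xrx
  modifiers:
  - X
initial_state: {}
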