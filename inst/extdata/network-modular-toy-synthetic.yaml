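# SYNTHETIC modular toy network (an artifact fixture of this package, not
# a published model). Three labelled modules: activation (S-driven I->A,
# A->I), output (A-driven production of observed R, R decay), feedback
# (slow A-driven accumulation of F, F-catalyzed deactivation of A).
# Designed so feedback is dispensable under a 0.25 s input pulse and
# required under 60 s continuous input (rise-peak-decline response).
species:
- S
- I
- A
- R
- F
reactions:
- reactants:
    I: 1
  products:
    A: 1
  param: k_act
  modifiers:
  - S
  module: activation
- reactants:
    A: 1
  products:
    I: 1
  param: k_deact
  module: activation
- reactants: []
  products:
    R: 1
  param: k_prod
  modifiers:
  - A
  module: output
- reactants:
    R: 1
  products: []
  param: k_dec
  module: output
- reactants: []
  products:
    F: 1
  param: k_fprod
  modifiers:
  - A
  module: feedback
- reactants:
    A: 1
  products:
    I: 1
  param: k_fb
  modifiers:
  - F
  module: feedback
- reactants:
    F: 1
  products: []
  param: k_fdec
  module: feedback
initial_state:
  I: 100.0
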