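# Complete 3-node network of first-order conversions (6 reactions).
# Benchmark prior network; generative truth k_AB=0.1 s^-1, k_BC=1 s^-1,
# all other rate constants 0. A starts at 100 molecules.
species:
- A
- B
- C
reactions:
- reactants:
    A: 1
  products:
    B: 1
  param: k_AB
- reactants:
    A: 1
  products:
    C: 1
  param: k_AC
- reactants:
    B: 1
  products:
    A: 1
  param: k_BA
- reactants:
    B: 1
  products:
    C: 1
  param: k_BC
- reactants:
    C: 1
  products:
    A: 1
  param: k_CA
- reactants:
    C: 1
  products:
    B: 1
  param: k_CB
initial_state:
  A: 100.0
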