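# Complete 5-node network of first-order conversions (20 reactions).
# Same generative truth as the 3-node benchmark (k_AB, k_BC).
species:
- A
- B
- C
- D
- E
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
    A: 1
  products:
    D: 1
  param: k_AD
- reactants:
    A: 1
  products:
    E: 1
  param: k_AE
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
    B: 1
  products:
    D: 1
  param: k_BD
- reactants:
    B: 1
  products:
    E: 1
  param: k_BE
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
- reactants:
    C: 1
  products:
    D: 1
  param: k_CD
- reactants:
    C: 1
  products:
    E: 1
  param: k_CE
- reactants:
    D: 1
  products:
    A: 1
  param: k_DA
- reactants:
    D: 1
  products:
    B: 1
  param: k_DB
- reactants:
    D: 1
  products:
    C: 1
  param: k_DC
- reactants:
    D: 1
  products:
    E: 1
  param: k_DE
- reactants:
    E: 1
  products:
    A: 1
  param: k_EA
- reactants:
    E: 1
  products:
    B: 1
  param: k_EB
- reactants:
    E: 1
  products:
    C: 1
  param: k_EC
- reactants:
    E: 1
  products:
    D: 1
  param: k_ED
initial_state:
  A: 100.0
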