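compound_column: compound
receptors:
  - id: green_algae
    name: Green algae
    endpoint: 96-EC50
  - id: daphnid
    name: Daphnid
    endpoint: 48-LC50
  - id: mysid
    name: Mysid
    endpoint: 96-LC50
  - id: fish
    name: Fish
    endpoint: 96-LC50
units: mg/L
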