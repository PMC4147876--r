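horizon: 10
failure_rates:
  implant:
    '0':
    - 0.0
    - 0.0
    - 0.0
    '1':
    - 0.054
    - 0.0655
    - 0.0805
    '2':
    - 0.046
    - 0.056
    - 0.069
    '3':
    - 0.038
    - 0.0465
    - 0.0575
    '4':
    - 0.03
    - 0.037
    - 0.046
    '5':
    - 0.022
    - 0.0275
    - 0.0345
    '6':
    - 0.014
    - 0.018
    - 0.023
  denture:
    '0':
    - 0.01
    - 0.05
    - 0.1
    '1':
    - 0.0325
    - 0.0485
    - 0.1065
    '2':
    - 0.029
    - 0.044
    - 0.094
    '3':
    - 0.0255
    - 0.0395
    - 0.0815
    '4':
    - 0.022
    - 0.035
    - 0.069
    '5':
    - 0.0185
    - 0.0305
    - 0.0565
    '6':
    - 0.015
    - 0.026
    - 0.044
satisfaction:
  '0': 0.63
  '1': 0.7
  '2': 0.77
  '3': 0.82
  '4': 0.85
  '5': 0.88
  '6': 0.89
repair_adjustment:
- 0.8
- 0.9
- 0.99
costs:
  labor:
    new_six:
      '1.0': 1472.67
      '2.3': 2990.86
      '3.5': 4392.27
    new_four:
      '1.0': 1130.07
      '2.3': 2199.98
      '3.5': 3190.67
    repair_implant:
      '1.0': 206.68
      '2.3': 267.35
      '3.5': 323.39
    repair_denture:
      '1.0': 65.19
      '2.3': 84.93
      '3.5': 103.16
  material:
    new_six: 5070.3
    new_four: 4507.82
    repair_implant: 160.0
    repair_denture: 50.0

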