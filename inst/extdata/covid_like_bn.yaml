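nodes:
- name: gender
  levels:
  - M
  - F
  parents: []
  cpt:
  - - 0.49
    - 0.51
- name: region
  levels:
  - London
  - South Central
  - South East Coast
  - South West
  - East of England
  - West Midlands
  - East Midlands
  - North West
  - North East
  - Yorkshire and The Humber
  parents: []
  cpt:
  - - 0.18
    - 0.09
    - 0.09
    - 0.08
    - 0.1
    - 0.1
    - 0.08
    - 0.13
    - 0.06
    - 0.09
- name: age
  levels:
  - '[18,30)'
  - '[30,40)'
  - '[40,50)'
  - '[50,60)'
  - '[60,70)'
  - '[70,80)'
  - '[80,95]'
  parents: []
  cpt:
  - - 0.2
    - 0.18
    - 0.17
    - 0.16
    - 0.12
    - 0.1
    - 0.07
- name: covid_diagnosis
  levels:
  - '0'
  - '1'
  parents:
  - age
  - region
  cpt:
  - - 0.817574
    - 0.182426
  - - 0.832018
    - 0.167982
  - - 0.845535
    - 0.154465
  - - 0.858149
    - 0.141851
  - - 0.869892
    - 0.130108
  - - 0.845535
    - 0.154465
  - - 0.817574
    - 0.182426
  - - 0.858149
    - 0.141851
  - - 0.869892
    - 0.130108
  - - 0.880797
    - 0.119203
  - - 0.890903
    - 0.109097
  - - 0.90025
    - 0.09975
  - - 0.880797
    - 0.119203
  - - 0.858149
    - 0.141851
  - - 0.858149
    - 0.141851
  - - 0.869892
    - 0.130108
  - - 0.880797
    - 0.119203
  - - 0.890903
    - 0.109097
  - - 0.90025
    - 0.09975
  - - 0.880797
    - 0.119203
  - - 0.858149
    - 0.141851
  - - 0.858149
    - 0.141851
  - - 0.869892
    - 0.130108
  - - 0.880797
    - 0.119203
  - - 0.890903
    - 0.109097
  - - 0.90025
    - 0.09975
  - - 0.880797
    - 0.119203
  - - 0.858149
    - 0.141851
  - - 0.851953
    - 0.148047
  - - 0.864127
    - 0.135873
  - - 0.875447
    - 0.124553
  - - 0.885948
    - 0.114052
  - - 0.895669
    - 0.104331
  - - 0.875447
    - 0.124553
  - - 0.851953
    - 0.148047
  - - 0.845535
    - 0.154465
  - - 0.858149
    - 0.141851
  - - 0.869892
    - 0.130108
  - - 0.880797
    - 0.119203
  - - 0.890903
    - 0.109097
  - - 0.869892
    - 0.130108
  - - 0.845535
    - 0.154465
  - - 0.858149
    - 0.141851
  - - 0.869892
    - 0.130108
  - - 0.880797
    - 0.119203
  - - 0.890903
    - 0.109097
  - - 0.90025
    - 0.09975
  - - 0.880797
    - 0.119203
  - - 0.858149
    - 0.141851
  - - 0.838891
    - 0.161109
  - - 0.851953
    - 0.148047
  - - 0.864127
    - 0.135873
  - - 0.875447
    - 0.124553
  - - 0.885948
    - 0.114052
  - - 0.864127
    - 0.135873
  - - 0.838891
    - 0.161109
  - - 0.851953
    - 0.148047
  - - 0.864127
    - 0.135873
  - - 0.875447
    - 0.124553
  - - 0.885948
    - 0.114052
  - - 0.895669
    - 0.104331
  - - 0.875447
    - 0.124553
  - - 0.851953
    - 0.148047
  - - 0.851953
    - 0.148047
  - - 0.864127
    - 0.135873
  - - 0.875447
    - 0.124553
  - - 0.885948
    - 0.114052
  - - 0.895669
    - 0.104331
  - - 0.875447
    - 0.124553
  - - 0.851953
    - 0.148047
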