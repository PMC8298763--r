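# SYNTHETIC code sets used by the cohort generator and the test suite.
# Codes are deliberately fictitious (S-prefixed) so that validation never
# depends on the illustrative real-code defaults in code_sets.yaml.

dbs:
  entries:
    - {system: PROC, code: "SDBS1", match: EXACT}
    - {system: PROC, code: "SDBS2", match: EXACT}
fall:
  entries:
    - {system: DX, code: "SFALL", match: PREFIX}
hallucinations:
  entries:
    - {system: DX, code: "SHAL1", match: EXACT}
    - {system: DX, code: "SHAL2", match: EXACT}
walker:
  required_setting: DME
  entries:
    - {system: DME, code: "SWALK1", match: EXACT}
wheelchair:
  required_setting: DME
  entries:
    - {system: DME, code: "SWHL", match: PREFIX}
specialty_bed:
  required_setting: DME
  entries:
    - {system: DME, code: "SBED1", match: EXACT}
dementia:
  entries:
    - {system: DX, code: "SDEM", match: PREFIX}
snf:
  required_setting: SNF
  entries:
    - {system: PROC, code: "SSNF1", match: EXACT}
hospice:
  required_setting: HOSPICE
  entries:
    - {system: PROC, code: "SHSP1", match: EXACT}
neurologist:
  entries:
    - {system: PROC, code: "SNEUR1", match: EXACT}
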