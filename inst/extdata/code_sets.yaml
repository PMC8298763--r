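# Default code sets for the nine claims-based severity indicators.
#
# IMPORTANT: these lists are ILLUSTRATIVE placeholders in the style of the
# relevant CPT / ICD-9-CM / HCPCS code families. They are not a validated
# claims phenotype and are expected to be replaced with locally curated,
# clinically reviewed lists before any substantive analysis. Codes are
# normalized on read (uppercased, dots stripped), so "331.0" and "3310"
# are equivalent.

dbs:
  entries:                     # CPT: DBS electrode/generator placement,
    - {system: PROC, code: "61863", match: EXACT}   # and programming
    - {system: PROC, code: "61864", match: EXACT}
    - {system: PROC, code: "61867", match: EXACT}
    - {system: PROC, code: "61868", match: EXACT}
    - {system: PROC, code: "61885", match: EXACT}
    - {system: PROC, code: "61886", match: EXACT}
    - {system: PROC, code: "95978", match: EXACT}
    - {system: PROC, code: "95979", match: EXACT}
fall:
  entries:                     # ICD-9 E-code accidental-fall family
    - {system: DX, code: "E880", match: PREFIX}
    - {system: DX, code: "E881", match: PREFIX}
    - {system: DX, code: "E882", match: PREFIX}
    - {system: DX, code: "E883", match: PREFIX}
    - {system: DX, code: "E884", match: PREFIX}
    - {system: DX, code: "E885", match: PREFIX}
    - {system: DX, code: "E886", match: PREFIX}
    - {system: DX, code: "E888", match: PREFIX}
hallucinations:
  entries:                     # selected hallucination diagnosis codes
    - {system: DX, code: "7801", match: PREFIX}
    - {system: DX, code: "3682", match: EXACT}
walker:
  required_setting: DME
  entries:                     # HCPCS walker family
    - {system: DME, code: "E0130", match: EXACT}
    - {system: DME, code: "E0135", match: EXACT}
    - {system: DME, code: "E0140", match: EXACT}
    - {system: DME, code: "E0141", match: EXACT}
    - {system: DME, code: "E0143", match: EXACT}
    - {system: DME, code: "E0147", match: EXACT}
    - {system: DME, code: "E0148", match: EXACT}
    - {system: DME, code: "E0149", match: EXACT}
wheelchair:
  required_setting: DME
  entries:                     # HCPCS manual/standard wheelchair families
    - {system: DME, code: "K000", match: PREFIX}
    - {system: DME, code: "E1130", match: EXACT}
    - {system: DME, code: "E1140", match: EXACT}
    - {system: DME, code: "E1160", match: EXACT}
    - {system: DME, code: "E1161", match: EXACT}
specialty_bed:
  required_setting: DME
  entries:                     # HCPCS hospital-bed family
    - {system: DME, code: "E025", match: PREFIX}
    - {system: DME, code: "E026", match: PREFIX}
    - {system: DME, code: "E027", match: PREFIX}
    - {system: DME, code: "E0290", match: EXACT}
dementia:
  entries:                     # ICD-9 dementia families (any subtype)
    - {system: DX, code: "290", match: PREFIX}
    - {system: DX, code: "294", match: PREFIX}
    - {system: DX, code: "3310", match: EXACT}
    - {system: DX, code: "33182", match: EXACT}
snf:
  required_setting: SNF
  entries:                     # SNF evaluation/management visit family
    - {system: PROC, code: "9930", match: PREFIX}
    - {system: PROC, code: "9931", match: PREFIX}
hospice:
  required_setting: HOSPICE
  entries:                     # hospice service family
    - {system: PROC, code: "Q5003", match: EXACT}
    - {system: PROC, code: "Q5004", match: EXACT}
    - {system: PROC, code: "Q5005", match: EXACT}
    - {system: PROC, code: "Q5006", match: EXACT}
    - {system: PROC, code: "Q5009", match: EXACT}
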