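# LED (levodopa equivalent dose) conversion table, transcribed from the
# standard systematic-review conversion algorithm for oral anti-PD
# medications. Factors multiply daily mg of the drug; COMT adjuncts
# instead contribute comt_multiplier x concurrent daily levodopa mg.
# strength_mg in pharmacy claims for carbidopa/levodopa combination
# products must be the mg of the levodopa moiety per unit.
# This table is user-editable; drug_id values are the keys pharmacy
# claims reference.

levodopa_ir:
  class: LEVODOPA_IR
  led_factor: 1.0
  counts_as_levodopa: true
levodopa_cr:
  class: LEVODOPA_CR
  led_factor: 0.75
  counts_as_levodopa: true
entacapone:
  class: COMT_ADJUNCT
  comt_multiplier: 0.33
  counts_as_levodopa: false
tolcapone:
  class: COMT_ADJUNCT
  comt_multiplier: 0.5
  counts_as_levodopa: false
pramipexole:
  class: DOPAMINE_AGONIST
  led_factor: 100.0
  counts_as_levodopa: false
ropinirole:
  class: DOPAMINE_AGONIST
  led_factor: 20.0
  counts_as_levodopa: false
rotigotine:
  class: DOPAMINE_AGONIST
  led_factor: 30.0
  counts_as_levodopa: false
bromocriptine:
  class: DOPAMINE_AGONIST
  led_factor: 10.0
  counts_as_levodopa: false
pergolide:
  class: DOPAMINE_AGONIST
  led_factor: 100.0
  counts_as_levodopa: false
selegiline:
  class: MAOB
  led_factor: 10.0
  counts_as_levodopa: false
rasagiline:
  class: MAOB
  led_factor: 100.0
  counts_as_levodopa: false
amantadine:
  class: OTHER_PD
  led_factor: 1.0
  counts_as_levodopa: false
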