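# Charlson Comorbidity Index, Deyo ICD-9-CM adaptation with the original
# Charlson weights. Prefixes are undotted ICD-9-CM stems; "a-b" denotes an
# inclusive range of equal-width stems. `supersedes` names a condition that
# must not also be counted when this one is present (standard hierarchy:
# complicated diabetes over diabetes, severe over mild liver disease,
# metastatic tumor over any malignancy). Editable configuration, not code.
conditions:
  - name: myocardial_infarction
    weight: 1
    prefixes: ["410", "412"]
  - name: congestive_heart_failure
    weight: 1
    prefixes: ["428"]
  - name: peripheral_vascular_disease
    weight: 1
    prefixes: ["441", "4439", "7854", "V434"]
  - name: cerebrovascular_disease
    weight: 1
    prefixes: ["430-438"]
  - name: dementia
    weight: 1
    prefixes: ["290"]
  - name: chronic_pulmonary_disease
    weight: 1
    prefixes: ["490-505", "5064"]
  - name: rheumatologic_disease
    weight: 1
    prefixes: ["7100", "7101", "7104", "7140", "7141", "7142", "71481", "725"]
  - name: peptic_ulcer_disease
    weight: 1
    prefixes: ["531-534"]
  - name: mild_liver_disease
    weight: 1
    prefixes: ["5712", "5714", "5715", "5716"]
  - name: diabetes
    weight: 1
    prefixes: ["2500", "2501", "2502", "2503", "2507"]
  - name: diabetes_with_complications
    weight: 2
    supersedes: diabetes
    prefixes: ["2504", "2505", "2506"]
  - name: hemiplegia_paraplegia
    weight: 2
    prefixes: ["342", "3441"]
  - name: renal_disease
    weight: 2
    prefixes: ["582", "5830-5837", "585", "586", "588"]
  - name: any_malignancy
    weight: 2
    prefixes: ["140-172", "174-195", "200-208"]
  - name: moderate_severe_liver_disease
    weight: 3
    supersedes: mild_liver_disease
    prefixes: ["4560-4562", "5722-5728"]
  - name: metastatic_solid_tumor
    weight: 6
    supersedes: any_malignancy
    prefixes: ["196-199"]
  - name: aids
    weight: 6
    prefixes: ["042-044"]
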