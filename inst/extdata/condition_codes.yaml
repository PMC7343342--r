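# Default undotted ICD-9-CM stems for the baseline comorbid-condition
# flags. The source tables print only condition names; these stems are a
# documented, editable default, not a validated code list.
conditions:
  neoplasms: ["140-239"]
  seizures: ["345", "7803"]
  asthma: ["493"]
  upper_respiratory_infection: ["460-466"]
  acute_chest_syndrome: ["5173"]
  infectious_disease: ["001-139"]
  fever: ["7806"]
  constipation: ["5640"]
  chronic_pain: ["3382", "3384"]
  iron_overload: ["2750"]
  avascular_necrosis: ["7334"]
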