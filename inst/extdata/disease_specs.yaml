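# Reference cohort definitions: eight diseases commonly used to benchmark
# cross-source patient identification. ICD-10 prefixes match codes and
# their subcategories; ranges expand at load time (E10-14 -> E10..E14).
# Drug (ingredient) lists are site-specific and therefore left empty here;
# supply your own curated lists per disease.
- name: "Alzheimer's disease"
  icd: [G300, G301, G308, G309]
- name: "Breast cancer"
  icd: [C50]
- name: "Diabetes"
  icd: [E10-14]
- name: "HIV infection"
  icd: [B20-24]
- name: "Hypercholesterolemia"
  icd: [E780]
- name: "Hypertension"
  icd: [I10-15]
- name: "Parkinson's disease"
  icd: [A521, G20, G211, G213, G214, G219]
- name: "Rheumatism"
  icd: [M123, M080, M05, M06]
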