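# Default code configuration for the sepsisldl pipeline.
#
# These lists are deliberately small and illustrative: they are sufficient to
# drive every filter in the pipeline and are meant to be replaced wholesale
# with site-specific code lists.  All matching against these lists is exact
# (string equality) except `icd_to_phecode`, which matches by code prefix.

# Billing codes that qualify an admission as an infection admission.
infection_codes:
  ICD9CM: ["038.9", "481", "486", "540.9", "566", "590.10", "599.0", "680.9", "682.9"]
  ICD10: ["A41.9", "J18.9", "L03.90", "N39.0"]

# Evidence of severe chronic illness (HIV, chronic kidney disease, liver
# disease, chemotherapy) in the year before the index admission excludes a
# patient from the measured-LDL cohort.
exclusion_condition_codes:
  ICD9CM: ["042", "196.9", "571.5", "572.2", "585.9", "V58.11"]
  ICD10: ["B20", "C78.00", "K74.60", "N18.6", "Z51.11"]

# Explicit severe-sepsis / septic-shock codes (highly specific).
severe_sepsis_shock_codes:
  ICD9CM: ["995.92", "785.52"]
  ICD10: ["R65.20", "R65.21"]

# Mechanical-ventilation procedure codes (respiratory-failure criterion).
ventilation_codes:
  PROC: ["96.70", "96.71", "96.72"]
  ICD10: ["5A1945Z"]

# Billing code for administration of a vasopressor (needed alongside
# dopamine/dobutamine for the cardiovascular-failure criterion).
vasopressor_admin_codes:
  PROC: ["00.17"]

# ADT-derived marker code for an ICU stay; the admission-level icu_flag is the
# primary source, this code is an alternative evidence route.
icu_codes:
  PROC: ["ICU"]

# Medication name lists (matched case- and whitespace-insensitively).
antibiotic_names:
  - vancomycin
  - ceftriaxone
  - cefepime
  - piperacillin-tazobactam
  - meropenem
  - levofloxacin
  - ciprofloxacin
  - azithromycin
  - ampicillin-sulbactam
  - doxycycline
statin_names:
  - atorvastatin
  - simvastatin
  - rosuvastatin
  - pravastatin
  - lovastatin
  - fluvastatin
  - pitavastatin
norepinephrine_names:
  - norepinephrine
  - norepinephrine bitartrate
  - levophed
dopamine_names:
  - dopamine
  - dopamine hydrochloride
dobutamine_names:
  - dobutamine
  - dobutamine hydrochloride

# Diagnosis code -> PheCode, by longest matching code prefix within a system.
icd_to_phecode:
  - {system: ICD9CM, prefix: "410", phecode: "411.2"}
  - {system: ICD9CM, prefix: "428", phecode: "428.2"}
  - {system: ICD9CM, prefix: "443", phecode: "443.9"}
  - {system: ICD9CM, prefix: "433", phecode: "433.2"}
  - {system: ICD9CM, prefix: "434", phecode: "433.2"}
  - {system: ICD9CM, prefix: "436", phecode: "433.2"}
  - {system: ICD9CM, prefix: "290", phecode: "290.1"}
  - {system: ICD9CM, prefix: "491", phecode: "496"}
  - {system: ICD9CM, prefix: "492", phecode: "496"}
  - {system: ICD9CM, prefix: "496", phecode: "496"}
  - {system: ICD9CM, prefix: "714", phecode: "714.1"}
  - {system: ICD9CM, prefix: "531", phecode: "531.2"}
  - {system: ICD9CM, prefix: "532", phecode: "531.2"}
  - {system: ICD9CM, prefix: "571.5", phecode: "571.51"}
  - {system: ICD9CM, prefix: "571.2", phecode: "571.51"}
  - {system: ICD9CM, prefix: "250", phecode: "250.1"}
  - {system: ICD9CM, prefix: "250.4", phecode: "250.2"}
  - {system: ICD9CM, prefix: "250.5", phecode: "250.2"}
  - {system: ICD9CM, prefix: "250.6", phecode: "250.2"}
  - {system: ICD9CM, prefix: "250.7", phecode: "250.2"}
  - {system: ICD9CM, prefix: "342", phecode: "344.1"}
  - {system: ICD9CM, prefix: "580", phecode: "585.1"}
  - {system: ICD9CM, prefix: "583", phecode: "585.1"}
  - {system: ICD9CM, prefix: "585", phecode: "585.1"}
  - {system: ICD9CM, prefix: "153", phecode: "153.2"}
  - {system: ICD9CM, prefix: "162", phecode: "165.1"}
  - {system: ICD9CM, prefix: "174", phecode: "174.1"}
  - {system: ICD9CM, prefix: "203", phecode: "204.1"}
  - {system: ICD9CM, prefix: "572", phecode: "571.8"}
  - {system: ICD9CM, prefix: "196", phecode: "198.1"}
  - {system: ICD9CM, prefix: "197", phecode: "198.1"}
  - {system: ICD9CM, prefix: "198", phecode: "198.1"}
  - {system: ICD9CM, prefix: "042", phecode: "071.1"}
  - {system: ICD10, prefix: "I21", phecode: "411.2"}
  - {system: ICD10, prefix: "I50", phecode: "428.2"}
  - {system: ICD10, prefix: "E11", phecode: "250.1"}
  - {system: ICD10, prefix: "J44", phecode: "496"}
  - {system: ICD10, prefix: "B20", phecode: "071.1"}
  - {system: ICD10, prefix: "C78", phecode: "198.1"}

# PheCode -> modified Charlson/Deyo comorbidity category.
phecode_to_charlson:
  - {phecode: "411.2", category: myocardial_infarction}
  - {phecode: "428.2", category: congestive_heart_failure}
  - {phecode: "443.9", category: peripheral_vascular_disease}
  - {phecode: "433.2", category: cerebrovascular_disease}
  - {phecode: "290.1", category: dementia}
  - {phecode: "496", category: chronic_pulmonary_disease}
  - {phecode: "714.1", category: rheumatic_disease}
  - {phecode: "531.2", category: peptic_ulcer_disease}
  - {phecode: "571.51", category: mild_liver_disease}
  - {phecode: "250.1", category: diabetes}
  - {phecode: "250.2", category: diabetes_complications}
  - {phecode: "344.1", category: hemiplegia_paraplegia}
  - {phecode: "585.1", category: renal_disease}
  - {phecode: "153.2", category: malignancy}
  - {phecode: "165.1", category: malignancy}
  - {phecode: "174.1", category: malignancy}
  - {phecode: "204.1", category: malignancy}
  - {phecode: "571.8", category: severe_liver_disease}
  - {phecode: "198.1", category: metastatic_solid_tumor}
  - {phecode: "071.1", category: aids_hiv}

# Category order (the covariate design column order).  `diabetes` and
# `diabetes_complications` are merged into a single `diabetes` indicator at
# covariate-construction time.
charlson_categories:
  - myocardial_infarction
  - congestive_heart_failure
  - peripheral_vascular_disease
  - cerebrovascular_disease
  - dementia
  - chronic_pulmonary_disease
  - rheumatic_disease
  - peptic_ulcer_disease
  - mild_liver_disease
  - diabetes
  - diabetes_complications
  - hemiplegia_paraplegia
  - renal_disease
  - malignancy
  - severe_liver_disease
  - metastatic_solid_tumor
  - aids_hiv
merge_diabetes: true

# Categories that the measured-LDL chronic-illness exclusions make
# structurally absent from that subcohort.
structural_absent_categories:
  - mild_liver_disease
  - severe_liver_disease
  - metastatic_solid_tumor
  - aids_hiv

# Representative diagnosis code planted by the synthetic generator for each
# comorbidity category (must be consistent with icd_to_phecode above).
category_example_codes:
  myocardial_infarction: {system: ICD9CM, code: "410.11"}
  congestive_heart_failure: {system: ICD9CM, code: "428.0"}
  peripheral_vascular_disease: {system: ICD9CM, code: "443.9"}
  cerebrovascular_disease: {system: ICD9CM, code: "434.91"}
  dementia: {system: ICD9CM, code: "290.0"}
  chronic_pulmonary_disease: {system: ICD9CM, code: "496"}
  rheumatic_disease: {system: ICD9CM, code: "714.0"}
  peptic_ulcer_disease: {system: ICD9CM, code: "531.30"}
  mild_liver_disease: {system: ICD9CM, code: "571.5"}
  diabetes: {system: ICD9CM, code: "250.00"}
  diabetes_complications: {system: ICD9CM, code: "250.42"}
  hemiplegia_paraplegia: {system: ICD9CM, code: "342.90"}
  renal_disease: {system: ICD9CM, code: "583.81"}
  malignancy: {system: ICD9CM, code: "153.9"}
  severe_liver_disease: {system: ICD9CM, code: "572.2"}
  metastatic_solid_tumor: {system: ICD9CM, code: "196.9"}
  aids_hiv: {system: ICD9CM, code: "042"}

# Two-sided significance threshold (Bonferroni-style constant for testing
# three outcomes).
significance_alpha: 0.0167
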