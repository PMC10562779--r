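# data.table is used via :: throughout; register NSE column names so static
# checks stay quiet.
utils::globalVariables(c(
  ".", ".N", "patient_id", "visit_date", "visit_type", "icd10_code", "code",
  "code_i", "code_j", "c_i", "c_j", "c_ij", "N", "sci", "phi", "t", "valid",
  "reason", "year", "n_out", "n_inp", "first", "last", "eligible", "sex",
  "birth_date", "index_date", "last_visit_date", "mean_age", "age_stratum",
  "chapter", "is_t2dm_index", "chronic_flag", "prevalence", "n_cond",
  "has_chronic", "n_sex", "community", "is_root", "harmonic", "from", "to",
  "weight", "excess", "ok", "n"
))

.datatable.aware <- TRUE
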