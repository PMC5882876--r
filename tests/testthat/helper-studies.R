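# Heavy end-to-end study runs shared by several accuracy tests, computed
# once per test session. Conditions: two-arm cohorts with ten causal SNPs
# per drug on disjoint sets (per-allele OR 1.8, n = 2000, p = 500) and null
# cohorts with 280 participants per arm at the same dimensionality.

.study_cache <- new.env(parent = emptyenv())

signal_study_runs <- function(n_seeds = 20) {
  key <- paste0("signal_", n_seeds)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  sets <- signal_snp_sets()
  runs <- lapply(seq_len(n_seeds), function(s) {
    co <- simulate_cohort(make_signal_config(seed = 1000 + s))
    pp <- preprocess_cohort(co, seed = derive_seed(1000 + s, 99))
    st <- run_full_study(pp, study_config(seed = s))
    list(same = c(A = st$per_drug$A$validation_report$auc,
                  B = st$per_drug$B$validation_report$auc),
         cross = c(A_on_B = st$cross_drug$A_on_B$auc,
                   B_on_A = st$cross_drug$B_on_A$auc),
         causal = c(A = length(intersect(st$per_drug$A$votes$retained, sets$A)),
                    B = length(intersect(st$per_drug$B$votes$retained, sets$B))))
  })
  .study_cache[[key]] <- runs
  runs
}

null_study_runs <- function(n_seeds = 10) {
  key <- paste0("null_", n_seeds)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  runs <- lapply(seq_len(n_seeds), function(s) {
    co <- simulate_cohort(make_null_config(seed = 2000 + s))
    pp <- preprocess_cohort(co, seed = derive_seed(2000 + s, 99))
    st <- suppressWarnings(run_full_study(pp, study_config(seed = s)))
    list(retained = c(A = length(st$per_drug$A$votes$retained),
                      B = length(st$per_drug$B$votes$retained)),
         auc = c(A = st$per_drug$A$validation_report$auc,
                 B = st$per_drug$B$validation_report$auc))
  })
  .study_cache[[key]] <- runs
  runs
}
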