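# Shared cohort builders for the test suite. The two canonical designs are
# (a) a null cohort (no effects anywhere) and (b) a cohort with ten causal
# SNPs per drug at a per-allele odds ratio of 1.8, on disjoint causal sets,
# one causal SNP per LD block.

signal_snp_sets <- function(p = 500, n_causal = 10) {
  n_causal <- min(n_causal, floor(p / 10))
  half <- floor(p / 2)
  list(A = sprintf("snp%04d", seq(1, by = 5, length.out = n_causal)),
       B = sprintf("snp%04d", seq(half + 1, by = 5, length.out = n_causal)))
}

make_signal_config <- function(seed, n = 2000, p = 500, or = 1.8,
                               shared_causal = FALSE, n_clinical = 10,
                               missing_rate = 0.05) {
  sets <- signal_snp_sets(p)
  if (shared_causal) sets$B <- sets$A
  causal <- unique(c(sets$A, sets$B))
  sim_config(n_participants = n, n_snps = p, ld_block_size = 5, ld_rho = 0.3,
             maf_range = c(0.05, 0.5), n_clinical = n_clinical,
             causal_features = sets,
             effect_sizes = setNames(rep(log(or), length(causal)), causal),
             intercepts = c(A = 0, B = 0),
             missing_rate = missing_rate, outcome_mode = "binary",
             seed = seed)
}

make_null_config <- function(seed, n = 560, p = 500, n_clinical = 10,
                             missing_rate = 0.05) {
  sim_config(n_participants = n, n_snps = p, ld_block_size = 5, ld_rho = 0.3,
             maf_range = c(0.05, 0.5), n_clinical = n_clinical,
             causal_features = list(A = character(), B = character()),
             effect_sizes = numeric(), intercepts = c(A = 0, B = 0),
             missing_rate = missing_rate, outcome_mode = "binary",
             seed = seed)
}

# brute-force pairwise AUC: the enumeration oracle the rank formula must match
auc_by_enumeration <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) total <- total + sum(a > neg) + 0.5 * sum(a == neg)
  total / (length(pos) * length(neg))
}

# trapezoidal integration of the empirical ROC curve
auc_by_trapezoid <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
}
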