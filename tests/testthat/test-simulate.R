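# Synthetic cohort generator: allele frequencies, LD structure, clinical
# variable types, outcome model, missingness, and determinism.

test_that("simulated allele frequencies match the configured MAF", {
  cfg <- sim_config(n_participants = 5000, n_snps = 20, ld_block_size = 1,
                    ld_rho = 0, maf_range = c(0.3, 0.3), n_clinical = 0,
                    seed = 101)
  g <- simulate_genotypes(cfg)
  freq <- colMeans(g) / 2
  expect_true(all(abs(freq - 0.3) < 0.02))
  expect_true(all(g %in% 0:2))
})

test_that("independent blocks give uncorrelated adjacent SNPs", {
  cfg <- sim_config(n_participants = 20000, n_snps = 20, ld_block_size = 1,
                    ld_rho = 0, maf_range = c(0.3, 0.3), n_clinical = 0,
                    seed = 102)
  g <- simulate_genotypes(cfg)
  r_adj <- sapply(seq_len(19), function(j) cor(g[, j], g[, j + 1]))
  expect_true(all(abs(r_adj) < 0.03))
})

test_that("within-block dosage correlation matches the bivariate-normal thresholding oracle", {
  m <- 0.3
  rho <- 0.9
  cfg <- sim_config(n_participants = 10000, n_snps = 2, ld_block_size = 2,
                    ld_rho = rho, maf_range = c(m, m), n_clinical = 0,
                    seed = 103)
  g <- simulate_genotypes(cfg)
  # oracle: E[D1 D2] = sum over threshold pairs of P(Z1 > a, Z2 > b) with
  # (Z1, Z2) standard bivariate normal at correlation rho, by quadrature
  t0 <- qnorm((1 - m)^2)
  t1 <- qnorm(1 - m^2)
  upper2 <- function(a, b) {
    integrate(function(z) dnorm(z) * (1 - pnorm((b - rho * z) / sqrt(1 - rho^2))),
              lower = a, upper = Inf, rel.tol = 1e-10)$value
  }
  e_d1d2 <- upper2(t0, t0) + upper2(t0, t1) + upper2(t1, t0) + upper2(t1, t1)
  mu_d <- 2 * m
  var_d <- 2 * m * (1 - m)
  r_oracle <- (e_d1d2 - mu_d^2) / var_d
  expect_equal(cor(g[, 1], g[, 2]), r_oracle, tolerance = 0.03)
})

test_that("clinical generator respects declared types and moments", {
  cfg0 <- sim_config(n_participants = 50, n_clinical = 0, seed = 104)
  expect_identical(ncol(simulate_clinical(cfg0)), 0L)

  cfg <- sim_config(n_participants = 4000, n_snps = 10, n_clinical = 8,
                    seed = 105)
  cl <- simulate_clinical(cfg)
  meta <- attr(cl, "meta")
  for (i in seq_len(nrow(meta))) {
    if (meta$type[i] %in% c("ordinal", "binary")) {
      expect_true(all(cl[, i] %in% meta$level_min[i]:meta$level_max[i]))
    } else {
      se_mean <- meta$sd[i] / sqrt(nrow(cl))
      expect_lt(abs(mean(cl[, i]) - meta$mean[i]), 3 * se_mean)
      expect_lt(abs(sd(cl[, i]) - meta$sd[i]), 3 * meta$sd[i] / sqrt(2 * nrow(cl)))
    }
  }
})

test_that("null outcome model gives 50% remission prevalence", {
  cfg <- sim_config(n_participants = 2000, n_snps = 10, n_clinical = 0,
                    seed = 106)
  co <- simulate_cohort(cfg)
  expect_lt(abs(mean(co$outcome) - 0.5), 0.03)
})

test_that("a single causal SNP recovers its odds ratio under logistic refit", {
  cfg <- sim_config(n_participants = 5000, n_snps = 10, ld_block_size = 1,
                    ld_rho = 0, maf_range = c(0.3, 0.3), n_clinical = 0,
                    causal_features = list(A = "snp0001", B = "snp0001"),
                    effect_sizes = c(snp0001 = log(2)),
                    seed = 107)
  co <- simulate_cohort(cfg)
  fit <- glm(co$outcome ~ co$features[, "snp0001"], family = binomial)
  expect_lt(abs(exp(coef(fit)[2]) - 2), 0.25)
})

test_that("HRSD-score mode yields the designed remission fraction and range", {
  cfg <- sim_config(n_participants = 4000, n_snps = 10, n_clinical = 0,
                    outcome_mode = "hrsd_score", seed = 108)
  co <- simulate_cohort(cfg)
  expect_true(all(co$outcome >= 0 & co$outcome <= 52))
  expect_true(all(co$outcome == round(co$outcome)))
  expect_lt(abs(mean(co$outcome <= 7) - 0.5), 0.03)
})

test_that("MCAR injection hits the configured rate and spares genotypes", {
  x <- matrix(rnorm(10000), 1000, 10,
              dimnames = list(NULL, paste0("c", 1:10)))
  expect_identical(inject_missingness(x, 0, seed = 1), x)
  masked <- inject_missingness(x, 0.1, seed = 2)
  expect_lt(abs(sum(is.na(masked)) - 1000), 100)
  expect_error(inject_missingness(x, 1), "rate")

  co <- simulate_cohort(sim_config(n_participants = 300, n_snps = 50,
                                   n_clinical = 6, missing_rate = 0.2,
                                   seed = 109))
  gen <- co$feature_meta$name[co$feature_meta$kind == "genetic"]
  cli <- co$feature_meta$name[co$feature_meta$kind == "clinical"]
  expect_identical(sum(is.na(co$features[, gen])), 0L)
  expect_gt(sum(is.na(co$features[, cli])), 0L)
})

test_that("the generator is bit-identical under a fixed seed", {
  cfg <- make_signal_config(seed = 110, n = 150, p = 60, n_clinical = 4)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("drug assignment is randomized independently of features", {
  # over 50 null cohorts, a 5%-level test of feature-by-arm association
  # should reject at close to the nominal rate
  pvals <- unlist(lapply(1:50, function(s) {
    co <- simulate_cohort(sim_config(n_participants = 200, n_snps = 5,
                                     ld_block_size = 1, n_clinical = 0,
                                     seed = 200 + s))
    sapply(1:5, function(j) {
      t.test(co$features[, j] ~ co$drug)$p.value
    })
  }))
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.08)
})

test_that("AUC of the true linear predictor matches a Monte-Carlo oracle", {
  cfg <- make_signal_config(seed = 111, n = 5000, p = 100, n_clinical = 0,
                            missing_rate = 0)
  co <- simulate_cohort(cfg)
  auc_obs <- roc_auc(plogis(co$eta), co$outcome)
  # oracle: an independent draw from the same generative law estimates the
  # analytic AUC of the generating model
  cfg2 <- make_signal_config(seed = 112, n = 5000, p = 100, n_clinical = 0,
                             missing_rate = 0)
  co2 <- simulate_cohort(cfg2)
  auc_oracle <- roc_auc(plogis(co2$eta), co2$outcome)
  expect_lt(abs(auc_obs - auc_oracle), 0.02)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(n_snps = 2, ld_block_size = 5), "ld_block_size")
  expect_error(
    sim_config(causal_features = list(A = "snp0001", B = character()),
               effect_sizes = numeric()),
    "effect_sizes")
  cfg <- sim_config(n_participants = 50, n_snps = 10, n_clinical = 0,
                    causal_features = list(A = "snp9999", B = character()),
                    effect_sizes = c(snp9999 = 1), seed = 1)
  g <- simulate_genotypes(cfg)
  expect_error(simulate_outcomes(g, rep("A", 50), cfg), "causal feature")
})
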