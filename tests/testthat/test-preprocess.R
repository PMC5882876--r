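# Predictor preparation: genotype QC filters, LD pruning, bagged-tree
# imputation with categorical rounding, remission derivation, and the
# stratified train/validation split.

test_that("MAF filter applies a strict > 0.01 bound on folded frequencies", {
  g <- cbind(mono = rep(0L, 100),
             rare3 = c(rep(1L, 3), rep(0L, 97)),    # MAF 3/200 = 0.015
             exact = c(rep(1L, 2), rep(0L, 98)),    # MAF 2/200 = 0.010 exactly
             common = rep(0:1, 50),
             flipped = rep(2L, 100) - c(rep(1L, 3), rep(0L, 97)))
  keep <- filter_maf(g, maf_min = 0.01)
  expect_false("mono" %in% keep)
  expect_true("rare3" %in% keep)
  expect_false("exact" %in% keep)     # strict inequality
  expect_true("common" %in% keep)
  expect_true("flipped" %in% keep)    # folded to 0.015
  expect_warning(filter_maf(cbind(g, gone = rep(NA_integer_, 100))),
                 "all-missing")
})

test_that("completeness filter keeps columns at >= 99% observed", {
  base <- rep(0:1, length.out = 430)
  g <- cbind(full = base,
             four = replace(base, 1:4, NA),   # 426/430 = 99.07%
             five = replace(base, 1:5, NA))   # 425/430 = 98.84%
  keep <- filter_completeness(g, 0.99)
  expect_true(all(c("full", "four") %in% keep))
  expect_false("five" %in% keep)
})

test_that("LD pruning drops later members of correlated groups, verified against pairwise r2", {
  set.seed(21)
  n <- 400
  x1 <- rbinom(n, 2, 0.4)
  mix <- function(a, w) {
    b <- rbinom(n, 2, 0.4)
    round(pmin(pmax(w * a + (1 - w) * b, 0), 2))
  }
  g <- cbind(s1 = x1, s2 = x1, s3 = mix(x1, 0.97), s4 = 2L - x1,
             s5 = rbinom(n, 2, 0.4))
  res <- ld_prune(g, ld_max = 0.8, window = 50)
  expect_identical(res$retained[1], "s1")
  expect_true("s5" %in% res$retained)
  expect_true(all(c("s2", "s4") %in% res$dropped$feature))  # r2 = 1 with s1
  # oracle: every dropped column's trigger really exceeds the bound, and
  # every retained pair is below it
  r2 <- cor(g)^2
  for (i in seq_len(nrow(res$dropped))) {
    expect_gt(r2[res$dropped$feature[i], res$dropped$by[i]], 0.8)
  }
  kept <- res$retained
  off <- r2[kept, kept][upper.tri(diag(length(kept)))]
  expect_true(all(off <= 0.8))
  expect_warning(ld_prune(cbind(g, cst = rep(1L, n))), "zero-variance")
})

test_that("QC filters give order-insensitive retained sets on complete data", {
  co <- simulate_cohort(make_null_config(30, n = 300, p = 120, n_clinical = 0,
                                         missing_rate = 0))
  g <- co$features
  a <- filter_maf(g)
  a <- g[, intersect(a, filter_completeness(g)), drop = FALSE]
  ra <- ld_prune(a)$retained
  b <- filter_completeness(g)
  b <- g[, intersect(b, filter_maf(g)), drop = FALSE]
  rb <- ld_prune(b)$retained
  expect_identical(ra, rb)
})

test_that("bagged-tree imputation recovers structure and leaves observed cells alone", {
  set.seed(31)
  n <- 300
  meta <- data.frame(name = c("a", "b", "c", "copy"),
                     type = c("continuous", "continuous", "continuous", "continuous"),
                     stringsAsFactors = FALSE)
  a <- rnorm(n)
  b <- rnorm(n)
  x <- cbind(a = a, b = b, c = 2 * a - b + rnorm(n, sd = 0.3), copy = a)
  expect_identical(impute_bagged_trees(x, meta, seed = 1)[, ],
                   x[, ])  # no missing values: unchanged

  # mask 10% of the noisy linear column: imputation must beat the marginal sd
  truth <- x[, "c"]
  xm <- x
  mis <- sample(n, 30)
  xm[mis, "c"] <- NA
  done <- impute_bagged_trees(xm, meta, n_trees = 25, seed = 2)
  expect_identical(done[-mis, "c"], x[-mis, "c"])
  rmse <- sqrt(mean((done[mis, "c"] - truth[mis])^2))
  expect_lt(rmse, sd(truth))

  # categorical copy-column: plurality vote recovers the donor almost always
  meta2 <- data.frame(name = c("o1", "o2"), type = c("ordinal", "ordinal"),
                      stringsAsFactors = FALSE)
  o <- rbinom(n, 4, 0.5)
  xo <- cbind(o1 = o, o2 = o)
  miso <- sample(n, 30)
  xo[miso, "o2"] <- NA
  doneo <- impute_bagged_trees(xo, meta2, n_trees = 25, seed = 3)
  expect_gte(mean(doneo[miso, "o2"] == o[miso]), 0.95)

  xall <- xo
  xall[, "o2"] <- NA
  expect_error(impute_bagged_trees(xall, meta2, seed = 4), "no observed values")
  expect_identical(impute_bagged_trees(xm, meta, n_trees = 10, seed = 9),
                   impute_bagged_trees(xm, meta, n_trees = 10, seed = 9))
})

test_that("categorical rounding snaps imputed cells to the nearest admissible value", {
  meta <- data.frame(name = c("item", "bin"), type = c("ordinal", "binary"),
                     level_min = c(0, 0), level_max = c(4, 1),
                     stringsAsFactors = FALSE)
  x <- cbind(item = c(2.6, 2.5, 3.9, 2.0), bin = c(0.8, 0.4, 1, 0))
  mask <- cbind(item = c(TRUE, TRUE, TRUE, FALSE),
                bin = c(TRUE, TRUE, FALSE, FALSE))
  out <- round_categorical(x, meta, mask)
  expect_identical(out[, "item"], c(3, 2, 4, 2))  # 2.5 ties toward 2
  expect_identical(out[, "bin"], c(1, 0, 1, 0))
  bad <- meta
  bad$level_min[1] <- 5
  expect_error(round_categorical(x, bad, mask), "admissible")
})

test_that("remission is HRSD-17 total of 7 or less", {
  expect_identical(derive_remission(c(0L, 7L, 8L, 52L)), c(1L, 1L, 0L, 0L))
  expect_error(derive_remission(53L), "52")
  expect_error(derive_remission(-1L), "52")
  expect_error(derive_remission(7.5), "integer")
})

test_that("the 65/35 split reproduces 280/150 and preserves strata", {
  set.seed(41)
  outcome <- rbinom(430, 1, 0.45)
  drug <- factor(sample(c("A", "B"), 430, TRUE))
  sp <- split_train_validation(outcome, drug, 0.65, seed = 7)
  expect_identical(length(sp$train), 280L)
  expect_identical(length(sp$validation), 150L)
  expect_identical(sort(c(sp$train, sp$validation)), 1:430)
  # per-stratum proportions off by at most one participant
  for (d in levels(drug)) for (o in 0:1) {
    idx <- which(drug == d & outcome == o)
    expect_lte(abs(sum(sp$train %in% idx) - 0.65 * length(idx)), 1)
  }
  expect_identical(split_train_validation(outcome, drug, 0.65, seed = 7), sp)
  sp2 <- split_train_validation(outcome, drug, 0.65, seed = 8)
  expect_false(identical(sp, sp2))

  y10 <- rep(0:1, each = 5)
  s10 <- split_train_validation(y10, NULL, 0.5, seed = 1)
  expect_identical(length(s10$train), 5L)
  expect_true(sum(y10[s10$train]) %in% 2:3)

  expect_warning(split_train_validation(c(0, 0, 0, 1), NULL, 0.5, seed = 1),
                 "fewer than 2")
})

test_that("preprocess_cohort completes features, derives remission and logs QC", {
  cfg <- sim_config(n_participants = 250, n_snps = 80, n_clinical = 8,
                    missing_rate = 0.1, outcome_mode = "hrsd_score", seed = 55)
  co <- simulate_cohort(cfg)
  pp <- preprocess_cohort(co, seed = 5)
  expect_false(anyNA(pp$features))
  expect_identical(pp$outcome_type, "binary")
  expect_identical(pp$outcome, derive_remission(pp$hrsd_total))
  log <- attr(pp, "qc_log")
  expect_true(is.list(log))
  expect_gt(log$n_clinical_imputed, 0)
  # genetic dosages remain integral after mode fill
  gen <- pp$feature_meta$name[pp$feature_meta$kind == "genetic"]
  expect_true(all(pp$features[, gen] %in% 0:2))
  # ordinal clinical columns are on admissible levels after rounding
  meta <- pp$feature_meta
  for (i in which(meta$type == "ordinal")) {
    expect_true(all(pp$features[, meta$name[i]] %in%
                      meta$level_min[i]:meta$level_max[i]))
  }
})
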