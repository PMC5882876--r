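# Elastic-net logistic regression: solver correctness against classical
# limits, KKT conditions, tuning behaviour, prediction identities, and the
# JSON export schema.

make_logit_data <- function(n = 200, p = 5, seed = 91, beta = NULL) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  if (is.null(beta)) beta <- c(1, -0.8, 0.5, rep(0, p - 3))
  y <- rbinom(n, 1, plogis(x %*% beta))
  list(x = x, y = y)
}

test_that("the unpenalized fit matches maximum-likelihood logistic regression", {
  d <- make_logit_data()
  m <- fit_enet_logistic(d$x, d$y, alpha = 1, lambda = 0)
  ref <- glm(d$y ~ d$x, family = binomial)
  expect_equal(unname(m$intercept), unname(coef(ref)[1]), tolerance = 1e-4)
  expect_equal(unname(m$coefficients), unname(coef(ref)[-1]), tolerance = 1e-4)
})

test_that("total shrinkage leaves only the prevalence intercept", {
  d <- make_logit_data(seed = 92)
  m <- fit_enet_logistic(d$x, d$y, alpha = 0.5, lambda = 1e6)
  expect_true(all(m$coefficients == 0))
  expect_equal(unname(m$intercept), qlogis(mean(d$y)), tolerance = 1e-8)
})

test_that("the lasso zeroes a pure-noise feature and satisfies the KKT conditions", {
  set.seed(93)
  n <- 300
  x <- cbind(sig = rnorm(n), noise = rnorm(n))
  y <- rbinom(n, 1, plogis(1.5 * x[, "sig"]))
  m <- fit_enet_logistic(x, y, alpha = 1, lambda = 0.08)
  expect_identical(unname(m$coefficients["noise"]), 0)
  expect_gt(m$coefficients["sig"], 0)
  kkt <- check_kkt(m, x, y)
  expect_true(kkt$ok)
  expect_lte(kkt$max_violation_zero, 1e-6)
})

test_that("the optimizer objective is non-increasing across sweeps", {
  for (s in 1:5) {
    d <- make_logit_data(seed = 940 + s, n = 120, p = 8,
                         beta = rnorm(8, sd = 0.7))
    m <- fit_enet_logistic(d$x, d$y, alpha = 0.5, lambda = 0.02)
    expect_true(all(diff(m$objective_trace) <= 1e-12))
  }
})

test_that("coefficient paths are continuous in lambda", {
  d <- make_logit_data(seed = 95)
  lams <- c(0.05, 0.0505, 0.051)
  fits <- lapply(lams, function(l) {
    fit_enet_logistic(d$x, d$y, alpha = 0.5, lambda = l)$coefficients
  })
  gap_near <- sqrt(sum((fits[[1]] - fits[[2]])^2))
  gap_far <- sqrt(sum((fits[[1]] - fits[[3]])^2))
  expect_lt(gap_near, 0.01)
  expect_lte(gap_near, gap_far + 1e-12)
})

test_that("prediction reproduces stored training output and de-standardizes exactly", {
  d <- make_logit_data(seed = 96)
  m <- fit_enet_logistic(d$x, d$y, alpha = 0.5, lambda = 0.02)
  expect_equal(predict(m, d$x), m$training$predictions, tolerance = 1e-10)
  # predictions through (standardized X, internal beta) equal the raw-scale path
  xs <- sweep(sweep(d$x, 2, m$standardization$mean), 2, m$standardization$sd, "/")
  beta_std <- m$coefficients * m$standardization$sd
  b0_std <- m$intercept + sum(m$coefficients * m$standardization$mean)
  expect_equal(as.vector(plogis(b0_std + xs %*% beta_std)), predict(m, d$x),
               tolerance = 1e-10)
  expect_error(predict(m, d$x[, 1:3]), "f4")
  # extra columns are ignored, order is by name
  shuffled <- cbind(d$x[, 5:1], junk = rnorm(nrow(d$x)))
  expect_equal(predict(m, shuffled), predict(m, d$x), tolerance = 1e-12)
})

test_that("an all-zero feature row with a zero intercept predicts one half", {
  m <- fit_intercept_only(rep(0:1, 25))
  expect_equal(unname(predict(m, matrix(0, 2, 0))), c(0.5, 0.5))
})

test_that("solver coefficients agree with glmnet on the same objective", {
  skip_if_not_installed("glmnet")
  d <- make_logit_data(seed = 97, n = 300)
  xs <- scale(d$x)
  for (alpha in c(0.3, 1)) {
    lam <- 0.03
    m <- fit_enet_logistic(xs, d$y, alpha = alpha, lambda = lam)
    g <- glmnet::glmnet(xs, d$y, family = "binomial", alpha = alpha,
                        lambda = lam, standardize = FALSE, thresh = 1e-12)
    expect_equal(unname(m$coefficients),
                 unname(as.vector(g$beta)), tolerance = 1e-4)
    expect_equal(unname(m$intercept), unname(g$a0), tolerance = 1e-4)
  }
})

test_that("tuning is deterministic, chance-level on noise, and powered under signal", {
  set.seed(98)
  n <- 400
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y_noise <- rbinom(n, 1, 0.5)
  t1 <- tune_enet(x, y_noise, repetitions = 25, seed = 7)
  t2 <- tune_enet(x, y_noise, repetitions = 25, seed = 7)
  expect_identical(t1[c("alpha", "lambda", "cv_auc")],
                   t2[c("alpha", "lambda", "cv_auc")])
  expect_lt(abs(t1$cv_auc - 0.5), 0.05)

  y_sig <- rbinom(n, 1, plogis(x %*% rep(log(2), 5)))
  t3 <- tune_enet(x, y_sig, repetitions = 25, seed = 7)
  expect_gt(t3$cv_auc, 0.7)
  expect_error(tune_enet(x, y_sig, alphas = 0.5), "2 alpha")
  expect_error(tune_enet(x, y_sig, nlambda = 5), "10 lambda")
})

test_that("more tuning repetitions reduce hyperparameter selection variance", {
  set.seed(99)
  n <- 150
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rbinom(n, 1, plogis(0.8 * x[, 1] - 0.6 * x[, 2]))
  pick <- function(reps, seed) {
    t <- tune_enet(x, y, repetitions = reps, seed = seed)
    log(t$lambda)
  }
  few <- sapply(1:10, function(s) pick(1, 100 + s))
  many <- sapply(1:10, function(s) pick(30, 100 + s))
  expect_lte(var(many), var(few))
})

test_that("model JSON export round-trips bit-exactly and validates its schema", {
  d <- make_logit_data(seed = 100, p = 3)
  m <- fit_enet_logistic(d$x, d$y, alpha = 0.5, lambda = 0.01,
                         kinds = c("genetic", "genetic", "clinical"))
  m$threshold <- 0.47
  m$drug <- "A"
  json <- export_model(m)
  m2 <- import_model(json)
  set.seed(1)
  newx <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, colnames(d$x)))
  expect_identical(predict(m2, newx), predict(m, newx))
  expect_identical(m2$threshold, m$threshold)
  doc <- jsonlite::fromJSON(json)
  expect_equal(doc$features$odds_ratio, exp(doc$features$coefficient),
               tolerance = 1e-12)
  expect_equal(doc$features$coefficient_per_sd,
               doc$features$coefficient * doc$features$sd, tolerance = 1e-12)

  bad <- sub('"schema_version": "1.0"', '"schema_version": "9.9"', json)
  expect_error(import_model(bad), "schema")

  minimal <- '{"schema_version":"1.0","intercept":-0.4,"features":[],"training":{"n":10}}'
  m3 <- import_model(minimal)
  expect_equal(unname(predict(m3, matrix(0, 3, 0))), rep(plogis(-0.4), 3))
})
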