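# Elastic-net logistic modelling: final fits, repeated cross-validated
# hyperparameter tuning, prediction, JSON export/import, KKT diagnostics.

MODEL_SCHEMA_VERSION <- "1.0"

standardize_columns <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv <= 0 | !is.finite(sdv)] <- 1
  list(x = sweep(sweep(x, 2, mu), 2, sdv, "/"), mean = mu, sd = sdv)
}

new_remit_model <- function(intercept, coefficients, kinds, alpha, lambda,
                            standardization, training, objective_trace = NULL) {
  structure(
    list(intercept = intercept,
         coefficients = coefficients,
         features = names(coefficients),
         feature_kinds = kinds,
         alpha = alpha, lambda = lambda,
         standardization = standardization,
         training = training,
         threshold = NULL,
         drug = NULL,
         objective_trace = objective_trace,
         schema_version = MODEL_SCHEMA_VERSION,
         package_version = as.character(utils::packageVersion("rxremit"))),
    class = "remit_model")
}

#' Fit an elastic-net logistic regression
#'
#' Minimizes, over intercept and coefficients `beta` on internally
#' standardized features (intercept unpenalized),
#' `(1/n) sum_i -[y_i eta_i - log(1 + exp(eta_i))] +
#'  lambda (alpha ||beta||_1 + (1-alpha)/2 ||beta||_2^2)`,
#' by coordinate descent inside an IRLS loop, stopping when the objective
#' changes by less than `tol` between sweeps. Coefficients are returned
#' de-standardized to the original feature scale (log-odds per unit; odds
#' ratio per feature is `exp(coefficient)`).
#'
#' @param x feature matrix restricted to the selected features (named
#'   columns, finite entries).
#' @param y binary outcome with both classes present.
#' @param alpha elastic-net mixing weight in `[0, 1]` (1 = lasso,
#'   0 = ridge).
#' @param lambda penalty strength, non-negative.
#' @param tol convergence tolerance on the objective change.
#' @param maxit maximum IRLS sweeps.
#' @param kinds optional per-feature kind labels (genetic/clinical), stored
#'   in the model.
#' @return An object of class `"remit_model"` storing intercept,
#'   per-feature coefficients, hyperparameters, standardization constants,
#'   training predictions and provenance.
#' @export
fit_enet_logistic <- function(x, y, alpha, lambda, tol = 1e-8, maxit = 250L,
                              kinds = NULL) {
  y <- as_binary01(y)
  check_both_classes(y)
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("feature matrix contains non-finite entries",
                               call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]", call. = FALSE)
  if (lambda < 0) stop("`lambda` must be non-negative", call. = FALSE)
  std <- standardize_columns(x)
  fit <- enet_path_cpp(std$x, as.numeric(y), alpha, lambda, tol, maxit)
  beta_std <- fit$beta[, 1]
  b0_std <- fit$b0[1]
  beta <- beta_std / std$sd
  b0 <- b0_std - sum(beta * std$mean)
  names(beta) <- colnames(x)
  preds <- as.vector(plogis(b0 + x %*% beta))
  model <- new_remit_model(
    intercept = b0, coefficients = beta, kinds = kinds,
    alpha = alpha, lambda = lambda,
    standardization = list(mean = std$mean, sd = std$sd),
    training = list(n = nrow(x), n_remitters = sum(y),
                    predictions = preds, labels = y),
    objective_trace = fit$trace[[1]])
  model
}

#' Intercept-only logistic model
#'
#' Fallback used when stability selection retains no features: a constant
#' model predicting the training prevalence for everyone.
#'
#' @param y binary training outcome.
#' @return A `"remit_model"` with no coefficients.
#' @export
fit_intercept_only <- function(y) {
  y <- as_binary01(y)
  check_both_classes(y)
  b0 <- qlogis(mean(y))
  new_remit_model(
    intercept = b0, coefficients = setNames(numeric(0), character(0)),
    kinds = character(0), alpha = NA_real_, lambda = NA_real_,
    standardization = list(mean = numeric(0), sd = numeric(0)),
    training = list(n = length(y), n_remitters = sum(y),
                    predictions = rep(plogis(b0), length(y)), labels = y))
}

#' Tune elastic-net hyperparameters by repeated cross-validation
#'
#' Evaluates every (alpha, lambda) grid point by mean out-of-fold AUC over
#' `repetitions` repetitions of `folds`-fold outcome-stratified
#' cross-validation and returns the maximizer, with exact ties broken
#' toward larger lambda and then larger alpha (parsimony). The lambda path
#' for each alpha is log-spaced over four decades down from `lambda_max`,
#' the smallest penalty that zeroes every coefficient. Folds whose training
#' part is single-class, or whose held-out part has only one class (AUC
#' undefined), are skipped. Deterministic given `seed`.
#'
#' @param x feature matrix (selected features).
#' @param y binary outcome.
#' @param alphas at least two mixing weights in `[0, 1]`.
#' @param nlambda at least 10 penalty values per alpha.
#' @param lambda_min_ratio ratio of the smallest to the largest lambda.
#' @param folds folds per repetition.
#' @param repetitions number of cross-validation repetitions.
#' @param seed integer seed.
#' @param tol,maxit solver controls.
#' @return An object of class `"enet_tuning"`: list with the selected
#'   `alpha`, `lambda`, its mean CV AUC `cv_auc`, and the full `grid` data
#'   frame.
#' @export
tune_enet <- function(x, y, alphas = c(0.1, 0.55, 1), nlambda = 12L,
                      lambda_min_ratio = 1e-4, folds = 5L, repetitions = 100L,
                      seed = 1L, tol = 1e-8, maxit = 100L) {
  y <- as_binary01(y)
  check_both_classes(y)
  x <- as.matrix(x)
  if (length(alphas) < 2L) stop("the grid needs at least 2 alpha values",
                                call. = FALSE)
  if (nlambda < 10L) stop("the grid needs at least 10 lambda values",
                          call. = FALSE)
  n <- nrow(x)
  std <- standardize_columns(x)
  g0 <- abs(crossprod(std$x, y - mean(y)) / n)
  lambdas <- vapply(alphas, function(a) {
    lmax <- max(g0) / max(a, 1e-3)
    exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
  }, numeric(nlambda))
  set.seed(derive_seed(seed, 40L))
  fold_ids <- matrix(0L, repetitions, n)
  for (r in seq_len(repetitions)) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold_ids[r, idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
  }
  res <- enet_cv_auc_cpp(x, as.numeric(y), fold_ids, alphas, lambdas,
                         tol, maxit)
  mean_auc <- res$auc_sum / pmax(res$n_folds, 1)
  mean_auc[res$n_folds == 0] <- NA_real_
  grid <- data.frame(alpha = rep(alphas, each = nlambda),
                     lambda = as.vector(lambdas),
                     mean_auc = as.vector(mean_auc),
                     n_folds = as.vector(res$n_folds))
  ok <- !is.na(grid$mean_auc)
  if (!any(ok)) stop("no cross-validation fold produced a usable AUC",
                     call. = FALSE)
  best_auc <- max(grid$mean_auc[ok])
  cand <- which(ok & abs(grid$mean_auc - best_auc) < 1e-12)
  cand <- cand[order(grid$lambda[cand], grid$alpha[cand], decreasing = TRUE)]
  pick <- cand[1]
  structure(list(alpha = grid$alpha[pick], lambda = grid$lambda[pick],
                 cv_auc = grid$mean_auc[pick], grid = grid,
                 repetitions = repetitions, folds = folds, seed = seed),
            class = "enet_tuning")
}

#' Predict remission probabilities
#'
#' `p_i = plogis(intercept + sum_k beta_k x_ik)` on the original feature
#' scale. Every model feature must be present in `newdata` by name; extra
#' columns are ignored.
#'
#' @param object a `"remit_model"`.
#' @param newdata matrix or data frame with named columns.
#' @param type `"response"` (probability) or `"link"` (log-odds).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.remit_model <- function(object, newdata, type = c("response", "link"),
                                ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$features, colnames(newdata))
  if (length(miss)) {
    stop("newdata is missing model feature(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  eta <- rep(object$intercept, nrow(newdata))
  if (length(object$features)) {
    eta <- eta + as.vector(newdata[, object$features, drop = FALSE] %*%
                             object$coefficients)
  }
  if (type == "link") eta else plogis(eta)
}

#' @export
print.remit_model <- function(x, ...) {
  cat(sprintf("Elastic-net logistic model (%d feature(s); alpha=%s, lambda=%s)\n",
              length(x$features),
              format(x$alpha), format(signif(x$lambda, 4))))
  if (!is.null(x$drug)) cat(sprintf("Training drug arm: %s\n", x$drug))
  cat(sprintf("Intercept (log-odds): %.4f; trained on n=%d\n",
              x$intercept, x$training$n))
  invisible(x)
}

#' Export a fitted model as a JSON document
#'
#' The document records feature names and kinds, coefficients with odds
#' ratios on both the per-unit and per-standard-deviation scale, intercept,
#' hyperparameters, standardization constants, the frozen classification
#' threshold (if any) and provenance, under a versioned schema.
#' `import_model(export_model(m))` reproduces predictions bit-exactly
#' (numbers are serialized at full precision).
#'
#' @param model a `"remit_model"`.
#' @param file optional path; when `NULL` the JSON text is returned.
#' @return The JSON string (invisibly when written to `file`).
#' @export
export_model <- function(model, file = NULL) {
  stopifnot(inherits(model, "remit_model"))
  feats <- data.frame(
    name = model$features,
    kind = if (length(model$feature_kinds)) model$feature_kinds
           else rep(NA_character_, length(model$features)),
    coefficient = unname(model$coefficients),
    odds_ratio = exp(unname(model$coefficients)),
    coefficient_per_sd = unname(model$coefficients * model$standardization$sd),
    odds_ratio_per_sd = exp(unname(model$coefficients * model$standardization$sd)),
    mean = unname(model$standardization$mean),
    sd = unname(model$standardization$sd),
    stringsAsFactors = FALSE)
  doc <- list(schema_version = model$schema_version,
              generator = "rxremit",
              package_version = model$package_version,
              drug = model$drug,
              alpha = model$alpha,
              lambda = model$lambda,
              intercept = model$intercept,
              threshold = model$threshold,
              features = feats,
              training = list(n = model$training$n,
                              n_remitters = model$training$n_remitters))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           pretty = TRUE, na = "null")
  if (is.null(file)) return(json)
  writeLines(json, file)
  invisible(json)
}

#' Import a model from its JSON export
#'
#' @param input path to a JSON file, or the JSON text itself.
#' @return A `"remit_model"` reproducing the exported model's predictions.
#' @export
import_model <- function(input) {
  doc <- jsonlite::fromJSON(input)
  if (is.null(doc$schema_version) ||
      !identical(as.character(doc$schema_version), MODEL_SCHEMA_VERSION)) {
    stop(sprintf("unsupported model schema version: %s (expected %s)",
                 doc$schema_version %||% "<missing>", MODEL_SCHEMA_VERSION),
         call. = FALSE)
  }
  feats <- doc$features
  if (is.null(feats) || length(feats) == 0 ||
      (is.data.frame(feats) && nrow(feats) == 0)) {
    coefs <- setNames(numeric(0), character(0))
    kinds <- character(0)
    std <- list(mean = numeric(0), sd = numeric(0))
  } else {
    coefs <- setNames(as.numeric(feats$coefficient), feats$name)
    kinds <- as.character(feats$kind)
    std <- list(mean = setNames(as.numeric(feats$mean), feats$name),
                sd = setNames(as.numeric(feats$sd), feats$name))
  }
  model <- new_remit_model(
    intercept = as.numeric(doc$intercept), coefficients = coefs,
    kinds = kinds,
    alpha = if (is.null(doc$alpha)) NA_real_ else as.numeric(doc$alpha),
    lambda = if (is.null(doc$lambda)) NA_real_ else as.numeric(doc$lambda),
    standardization = std,
    training = list(n = doc$training$n %||% NA_integer_,
                    n_remitters = doc$training$n_remitters %||% NA_integer_,
                    predictions = NULL, labels = NULL))
  model$threshold <- if (is.null(doc$threshold)) NULL else as.numeric(doc$threshold)
  model$drug <- if (is.null(doc$drug)) NULL else as.character(doc$drug)
  model
}

#' Check Karush-Kuhn-Tucker conditions of a fitted model
#'
#' On the standardized feature scale, stationarity requires
#' `(1/n) x_k' (y - p) = lambda alpha s_k + lambda (1 - alpha) beta_k` with
#' `s_k = sign(beta_k)` for active coefficients and `|s_k| <= 1` for zero
#' coefficients, i.e. `|(1/n) x_k' (y - p)| <= lambda alpha + tol` at every
#' zero.
#'
#' @param model a `"remit_model"`.
#' @param x,y the training data the model was fitted on.
#' @param tol slack added to the subgradient bound.
#' @return List with `ok`, `max_violation_zero`, `max_violation_active`.
#' @export
check_kkt <- function(model, x, y, tol = 1e-6) {
  y <- as_binary01(y)
  x <- as.matrix(x)[, model$features, drop = FALSE]
  n <- nrow(x)
  xs <- sweep(sweep(x, 2, model$standardization$mean), 2,
              model$standardization$sd, "/")
  p <- predict(model, x)
  g <- as.vector(crossprod(xs, y - p)) / n
  beta_std <- model$coefficients * model$standardization$sd
  zero <- beta_std == 0
  viol_zero <- if (any(zero)) {
    max(abs(g[zero]) - model$lambda * model$alpha, 0)
  } else 0
  viol_active <- if (any(!zero)) {
    max(abs(g[!zero] - model$lambda * model$alpha * sign(beta_std[!zero]) -
              model$lambda * (1 - model$alpha) * beta_std[!zero]))
  } else 0
  list(ok = viol_zero <= tol && viol_active <= 100 * tol,
       max_violation_zero = viol_zero,
       max_violation_active = viol_active)
}
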