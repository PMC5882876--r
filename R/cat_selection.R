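# Variable selection: correlation-adjusted t-scores (CAT), local false
# discovery rates (LFDR), and majority voting over repeated cross-validation.

#' Analytic shrinkage intensity for the feature correlation matrix
#'
#' Estimates how far the empirical correlation matrix should be shrunk
#' toward the identity:
#' `lambda = clamp( sum_{k<l} Var(r_kl) / sum_{k<l} r_kl^2 , 0, 1)`,
#' where `Var(r_kl)` is the empirical variance of the per-observation
#' products of standardized residuals scaled by `n / (n-1)^3`. A value of 1
#' means total shrinkage (identity target); under independence with p >> n
#' the estimate approaches 1, while structure with negligible sampling
#' variance drives it toward 0. Computed without materializing the p x p
#' correlation matrix (O(p n^2) via the singular values of the standardized
#' data).
#'
#' @param x numeric matrix (observations x features); columns are centered
#'   and scaled internally. Zero-variance columns are ignored.
#' @return Shrinkage intensity in `[0, 1]`.
#' @export
shrinkage_intensity <- function(x) {
  n <- nrow(x)
  if (n < 3L) {
    stop("at least 3 observations are required to estimate correlation shrinkage",
         call. = FALSE)
  }
  cen <- sweep(x, 2, colMeans(x))
  ss <- colSums(cen^2)
  keep <- ss > 0
  p_eff <- sum(keep)
  if (p_eff < 2L) return(1)
  w <- sweep(cen[, keep, drop = FALSE], 2, sqrt(ss[keep] / (n - 1)), "/")
  d_std <- svd(w / sqrt(n - 1), nu = 0, nv = 0)$d
  shrinkage_from_svd(w, d_std, n, p_eff)
}

# core of the intensity estimator, reusing an existing SVD:
# w has column sums of squares n-1; d_std are the singular values of
# w / sqrt(n-1), so sum(d_std^4) is the squared Frobenius norm of the
# empirical correlation matrix
shrinkage_from_svd <- function(w, d_std, n, p_eff) {
  sum_r2_off <- sum(d_std^4) - p_eff
  if (sum_r2_off <= 1e-12) return(1)
  term1 <- sum(rowSums(w^2)^2)
  frob_wtw <- (n - 1)^2 * sum(d_std^4)
  s_all <- term1 - frob_wtw / n
  diag_term <- sum((w^2 - (n - 1) / n)^2)
  s_off <- s_all - diag_term
  lambda <- n / (n - 1)^3 * s_off / sum_r2_off
  min(1, max(0, lambda))
}

#' Correlation-adjusted t-scores
#'
#' Computes, for a binary outcome, the standardized mean-difference scores
#' `delta_k = (xbar_{k,1} - xbar_{k,0}) / (m * s_k)` with
#' `m = sqrt(1/n1 + 1/n0)` and `s_k` the pooled within-group standard
#' deviation, then decorrelates them:
#' `tau = R_shrunk^{-1/2} delta` with
#' `R_shrunk = lambda * I + (1 - lambda) * R_empirical`, `lambda` from
#' [shrinkage_intensity()] on the group-centered residuals. The inverse
#' square root uses the spectral decomposition of the low-rank part of
#' `R_empirical` (cost O(p n^2); the p x p matrix is never formed). At
#' `lambda = 1` the scores equal `delta` exactly.
#'
#' @param x feature matrix (observations x features, named columns).
#' @param y binary outcome (0/1, logical, or 2-level factor).
#' @param lambda optional fixed shrinkage intensity in `[0, 1]`; by default
#'   estimated from the data. Values below `1e-6` are floored there so the
#'   matrix square root stays well defined.
#' @return An object of class `"cat_scores"`: list with `scores` (tau),
#'   `delta`, `lambda_corr`, `n1`, `n0`, `s` (pooled sds after the variance
#'   floor), `m`, and `zero_variance` (flagged features scored 0).
#' @export
cat_scores <- function(x, y, lambda = NULL) {
  y <- as_binary01(y)
  check_both_classes(y)
  n <- nrow(x)
  p <- ncol(x)
  if (p < 1L) stop("at least one feature is required", call. = FALSE)
  if (n < 3L) stop("at least 3 observations are required", call. = FALSE)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  m <- sqrt(1 / n1 + 1 / n0)
  mu1 <- colMeans(x[y == 1L, , drop = FALSE])
  mu0 <- colMeans(x[y == 0L, , drop = FALSE])
  e <- x
  e[y == 1L, ] <- sweep(x[y == 1L, , drop = FALSE], 2, mu1)
  e[y == 0L, ] <- sweep(x[y == 0L, , drop = FALSE], 2, mu0)
  ss <- colSums(e^2)
  # flag only truly constant columns; a perfectly separating feature has
  # zero within-group variance but carries maximal information and is
  # scored through the variance floor
  zero_var <- apply(x, 2, function(v) length(unique(v)) == 1L)
  no_resid <- ss == 0
  s <- sqrt(ss / (n - 2))
  med_s <- median(s[!no_resid])
  if (!is.finite(med_s) || med_s <= 0) med_s <- 1
  s <- pmax(s, 1e-8 * med_s)
  delta <- (mu1 - mu0) / (m * s)
  delta[zero_var] <- 0
  tau <- delta
  scorable <- !no_resid  # residual-free columns keep tau = delta (identity row)
  if (any(scorable)) {
    # unit-norm residual columns: crossprod(w) is the empirical correlation
    # matrix of the group-centered residuals, and its singular values (times
    # sqrt(n-1)) are the ones the shrinkage-intensity estimator needs, so a
    # single SVD serves both the intensity and the decorrelation
    w <- sweep(e[, scorable, drop = FALSE], 2, sqrt(ss[scorable]), "/")
    sv <- svd(w, nu = 0)
    if (is.null(lambda)) {
      lambda <- if (sum(scorable) >= 2L) {
        shrinkage_from_svd(w * sqrt(n - 1), sv$d, n, sum(scorable))
      } else 1
    }
    if (lambda < 0 || lambda > 1) stop("`lambda` must be in [0, 1]", call. = FALSE)
    lam <- max(lambda, 1e-6)
    d_sub <- delta[scorable]
    if (lam < 1) {
      scale_vec <- 1 / sqrt(lam + (1 - lam) * sv$d^2) - 1 / sqrt(lam)
      tau_sub <- d_sub / sqrt(lam) +
        as.vector(sv$v %*% (scale_vec * crossprod(sv$v, d_sub)))
    } else {
      tau_sub <- d_sub
    }
    tau[scorable] <- tau_sub
  } else {
    if (is.null(lambda)) lambda <- 1
  }
  names(tau) <- colnames(x)
  structure(
    list(scores = tau, delta = setNames(delta, colnames(x)),
         lambda_corr = lambda, n1 = n1, n0 = n0,
         s = setNames(s, colnames(x)), m = m,
         zero_variance = setNames(zero_var, colnames(x))),
    class = "cat_scores")
}

kde_gauss <- function(at, obs, bw) {
  # Gaussian kernel density of `obs` evaluated at `at`
  rowMeans(dnorm(outer(at, obs, "-"), sd = bw))
}

#' Local false discovery rates from a score vector
#'
#' Fits the two-component model `f(s) = eta0 f0(s) + (1 - eta0) f1(s)` with
#' a Gaussian null `f0 = N(0, sigma0^2)`: `sigma0` is estimated robustly
#' from the central scores (median absolute score / qnorm(0.75)), the
#' marginal `f` by a Gaussian kernel density with Silverman bandwidth, and
#' the null proportion as `eta0 = min(1, f(0) / f0(0))`. Two numerical
#' details keep the density ratio calibrated: the null component is
#' evaluated at the kernel resolution (`N(0, sigma0^2 + h^2)`, matching the
#' variance the kernel estimate carries), and each score's own kernel is
#' excluded when evaluating the marginal at that score (the self-kernel
#' mass `K(0)/p` is negligible in the bulk but dominates in the far tail,
#' where it would spuriously halve the local FDR of isolated null scores).
#' Each feature's local FDR is `clamp(eta0 f0(tau_k) / f(tau_k), 0, 1)`,
#' made non-increasing in `|tau|` by isotonic regression, so it can be read
#' as the probability that the feature is non-informative given its score.
#'
#' @param scores numeric vector of at least 50 scores.
#' @return An object of class `"lfdr_estimate"`: list with `lfdr` (named as
#'   `scores`), `eta0`, `sigma0`, `bandwidth`.
#' @export
estimate_lfdr <- function(scores) {
  p <- length(scores)
  if (p < 50L) {
    stop("local FDR estimation needs at least 50 scores", call. = FALSE)
  }
  if (length(unique(scores)) == 1L) {
    warning("degenerate score vector (all values equal): all local FDRs set to 1")
    return(structure(list(lfdr = setNames(rep(1, p), names(scores)),
                          eta0 = 1, sigma0 = NA_real_, bandwidth = NA_real_),
                     class = "lfdr_estimate"))
  }
  sigma0 <- median(abs(scores)) / qnorm(0.75)
  sigma0 <- max(sigma0, 1e-8)
  h <- bw.nrd0(scores)
  # the kernel estimate of the marginal carries variance sigma^2 + h^2, so
  # the null component is evaluated at the same kernel resolution: without
  # this, the ratio f0/f decays spuriously in |score| under a pure null
  s0k <- sqrt(sigma0^2 + h^2)
  f0 <- dnorm(scores, 0, s0k)
  fm_raw <- kde_gauss(scores, scores, h)
  fm <- pmax((p * fm_raw - dnorm(0, 0, h)) / (p - 1), 1e-300)
  fm0 <- kde_gauss(0, scores, h)
  eta0 <- min(1, fm0 / dnorm(0, 0, s0k))
  lfdr <- pmin(1, pmax(0, eta0 * f0 / fm))
  o <- order(abs(scores))
  iso <- isoreg(seq_along(o), -lfdr[o])
  lfdr[o] <- pmin(1, pmax(0, -iso$yf))
  structure(list(lfdr = setNames(lfdr, names(scores)), eta0 = eta0,
                 sigma0 = sigma0, bandwidth = h),
            class = "lfdr_estimate")
}

#' Stability selection by repeated cross-validated voting
#'
#' Runs `repetitions` repetitions of `folds`-fold cross-validation (100
#' rounds at the defaults). In each round the held-out fifth is set aside
#' and CAT scores plus local FDRs are computed on the remaining
#' four-fifths; a feature collects a vote when its local FDR falls below
#' `lfdr_threshold` (0.8 by default, a deliberately liberal bound). Features
#' voted for more times than not — strictly more than half of the executed
#' rounds — are retained. Folds are stratified by outcome; rounds whose
#' in-fold data contain a single outcome class are skipped with a warning
#' and removed from the vote denominator. Deterministic given `seed`.
#'
#' @param x feature matrix for one drug arm's training participants.
#' @param y binary outcome.
#' @param repetitions number of cross-validation repetitions.
#' @param folds folds per repetition (at least 2).
#' @param lfdr_threshold vote threshold on the local FDR.
#' @param seed integer seed.
#' @return An object of class `"selection_votes"`: list with `votes` (data
#'   frame: `feature`, `votes`, `rounds`, `retained`), `retained` (character
#'   vector), `rounds` executed, and the parameters.
#' @export
stability_select <- function(x, y, repetitions = 20L, folds = 5L,
                             lfdr_threshold = 0.8, seed = 1L) {
  y <- as_binary01(y)
  check_both_classes(y)
  if (folds < 2L) stop("`folds` must be at least 2", call. = FALSE)
  n <- nrow(x)
  p <- ncol(x)
  votes <- setNames(integer(p), colnames(x))
  rounds_run <- 0L
  skipped <- 0L
  set.seed(derive_seed(seed, 30L))
  for (r in seq_len(repetitions)) {
    fold_id <- integer(n)
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold_id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2L) {
        skipped <- skipped + 1L
        next
      }
      cs <- cat_scores(x[tr, , drop = FALSE], y[tr])
      lf <- estimate_lfdr(cs$scores)
      votes <- votes + as.integer(lf$lfdr < lfdr_threshold)
      rounds_run <- rounds_run + 1L
    }
  }
  if (skipped > 0L) {
    warning(sprintf("%d round(s) skipped (single outcome class in fold) and excluded from the vote denominator",
                    skipped))
  }
  retained <- names(votes)[votes > rounds_run / 2]
  structure(
    list(votes = data.frame(feature = names(votes),
                            votes = unname(votes),
                            rounds = rounds_run,
                            retained = unname(votes) > rounds_run / 2,
                            stringsAsFactors = FALSE),
         retained = retained, rounds = rounds_run,
         repetitions = repetitions, folds = folds,
         lfdr_threshold = lfdr_threshold, seed = seed),
    class = "selection_votes")
}

#' @export
print.selection_votes <- function(x, ...) {
  cat(sprintf("Stability selection: %d rounds (%d x %d-fold CV), LFDR < %g\n",
              x$rounds, x$repetitions, x$folds, x$lfdr_threshold))
  cat(sprintf("Retained %d of %d features (vote > %g)\n",
              length(x$retained), nrow(x$votes), x$rounds / 2))
  invisible(x)
}
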