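#' Simulation settings for a randomized two-arm pharmacogenetic cohort
#'
#' Defines the generative model for a synthetic cohort of depressed patients
#' randomized between two antidepressants ("A" and "B"): SNP dosages in
#' linkage-disequilibrium (LD) blocks, clinical/demographic predictors,
#' drug-specific sparse logistic effects on remission, and MCAR missingness
#' in the clinical variables. Defaults emulate a GENDEP-like trial: 430
#' participants, LD-blocked common SNPs with minor allele frequency (MAF)
#' drawn uniformly from `maf_range`, and ~50% remission prevalence per arm.
#'
#' @param n_participants number of participants.
#' @param n_snps number of SNPs; must be at least `ld_block_size`.
#' @param ld_block_size number of SNPs per LD block. Blocks are mutually
#'   independent; within a block, latent Gaussians follow an AR(1) process
#'   with correlation `ld_rho`.
#' @param ld_rho latent AR(1) correlation in `[0, 1)`.
#' @param maf_range length-2 vector of minor allele frequency bounds, inside
#'   `(0, 0.5]`. SNP-wise MAFs are drawn uniformly from this interval. Keep
#'   the lower bound above 0.01 if generated SNPs should survive the default
#'   MAF filter.
#' @param n_clinical number of clinical/demographic predictors (a mix of
#'   ordinal items, binary indicators and continuous measures).
#' @param causal_features named list (one element per drug label) of feature
#'   identifiers carrying an effect on remission in that arm. Sets may
#'   overlap or be disjoint between drugs.
#' @param effect_sizes named numeric vector of log-odds per unit of the
#'   feature (per allele for SNP dosages), covering every causal feature.
#' @param intercepts named numeric vector of per-drug log-odds intercepts.
#'   Zero gives 50% remission prevalence.
#' @param missing_rate MCAR missingness probability in `[0, 1)` applied to
#'   clinical columns only.
#' @param outcome_mode `"binary"` for a Bernoulli remission indicator, or
#'   `"hrsd_score"` for an integer HRSD-17 total in `[0, 52]` constructed so
#'   that `P(score <= 7) = plogis(eta)`.
#' @param seed master seed; all sub-generators derive their streams from it
#'   via [derive_seed()].
#' @return An object of class `"sim_config"`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_participants = 430L,
                       n_snps = 1000L,
                       ld_block_size = 5L,
                       ld_rho = 0.3,
                       maf_range = c(0.05, 0.5),
                       n_clinical = 20L,
                       causal_features = list(A = character(), B = character()),
                       effect_sizes = numeric(),
                       intercepts = c(A = 0, B = 0),
                       missing_rate = 0.05,
                       outcome_mode = c("binary", "hrsd_score"),
                       seed = 1L) {
  outcome_mode <- match.arg(outcome_mode)
  if (n_participants < 1 || n_snps < 1 || ld_block_size < 1 || n_clinical < 0) {
    stop("cohort dimensions must be positive (n_clinical may be zero)", call. = FALSE)
  }
  if (n_snps < ld_block_size) {
    stop("`n_snps` must be at least `ld_block_size`", call. = FALSE)
  }
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("`maf_range` must lie within (0, 0.5] with lower <= upper", call. = FALSE)
  }
  if (ld_rho < 0 || ld_rho >= 1) stop("`ld_rho` must be in [0, 1)", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must be in [0, 1)", call. = FALSE)
  }
  if (!is.list(causal_features) || is.null(names(causal_features))) {
    stop("`causal_features` must be a named list keyed by drug label", call. = FALSE)
  }
  causal <- unique(unlist(causal_features, use.names = FALSE))
  if (length(causal) && !all(causal %in% names(effect_sizes))) {
    stop("every causal feature needs an entry in `effect_sizes`", call. = FALSE)
  }
  drugs <- names(causal_features)
  if (!all(drugs %in% names(intercepts))) {
    stop("`intercepts` must name every drug in `causal_features`", call. = FALSE)
  }
  structure(
    list(n_participants = as.integer(n_participants),
         n_snps = as.integer(n_snps),
         ld_block_size = as.integer(ld_block_size),
         ld_rho = ld_rho,
         maf_range = maf_range,
         n_clinical = as.integer(n_clinical),
         causal_features = causal_features,
         effect_sizes = effect_sizes,
         intercepts = intercepts,
         missing_rate = missing_rate,
         outcome_mode = outcome_mode,
         seed = as.integer(seed)),
    class = "sim_config")
}

snp_names <- function(p) sprintf("snp%04d", seq_len(p))
clinical_names <- function(q) sprintf("clin%02d", seq_len(q))

#' Simulate LD-blocked SNP dosage genotypes
#'
#' Each SNP draws its MAF uniformly from `config$maf_range`. Within an LD
#' block, latent standard Gaussians follow an AR(1) process with correlation
#' `ld_rho` and are thresholded at the Hardy-Weinberg quantiles
#' `P(0) = (1-MAF)^2`, `P(1) = 2 MAF (1-MAF)`, `P(2) = MAF^2`, producing
#' correlated additive dosages in `{0, 1, 2}`. Blocks are independent.
#'
#' @param config a [sim_config()].
#' @return An `n x n_snps` integer dosage matrix with an attribute `"maf"`
#'   carrying the drawn allele frequencies.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_participants
  p <- config$n_snps
  b <- config$ld_block_size
  rho <- config$ld_rho
  set.seed(derive_seed(config$seed, 1L))
  maf <- runif(p, config$maf_range[1], config$maf_range[2])
  g <- matrix(0L, n, p, dimnames = list(NULL, snp_names(p)))
  blocks <- split(seq_len(p), ceiling(seq_len(p) / b))
  for (idx in blocks) {
    m <- length(idx)
    z <- matrix(rnorm(n * m), n, m)
    if (m > 1L && rho > 0) {
      for (j in 2:m) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
    }
    for (j in seq_len(m)) {
      mj <- maf[idx[j]]
      t0 <- qnorm((1 - mj)^2)   # below: dosage 0
      t1 <- qnorm(1 - mj^2)     # above: dosage 2
      g[, idx[j]] <- (z[, j] > t0) + (z[, j] > t1)
    }
  }
  attr(g, "maf") <- setNames(maf, colnames(g))
  g
}

#' Simulate clinical and demographic predictors
#'
#' Produces a mix of ordinal scale items (0-4 and 0-2 ranges, emulating
#' HRSD/MADRS/BDI items), binary indicators (smoking-like) and continuous
#' measures (age-like: mean 42, sd 12; BMI-like: mean 25.5, sd 4), cycling
#' through these templates. Each column's type and admissible range are
#' declared in the returned metadata so categorical rounding after
#' imputation can be checked.
#'
#' @param config a [sim_config()].
#' @return A numeric `n x n_clinical` matrix with attribute `"meta"`, a data
#'   frame with columns `name`, `type` (`ordinal`, `binary`, `continuous`),
#'   `level_min`, `level_max`, `mean`, `sd`.
#' @export
simulate_clinical <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_participants
  q <- config$n_clinical
  nm <- clinical_names(q)
  meta <- data.frame(name = character(0), type = character(0),
                     level_min = numeric(0), level_max = numeric(0),
                     mean = numeric(0), sd = numeric(0),
                     stringsAsFactors = FALSE)
  x <- matrix(numeric(0), n, 0)
  if (q == 0L) {
    attr(x, "meta") <- meta
    return(x)
  }
  set.seed(derive_seed(config$seed, 2L))
  cols <- vector("list", q)
  rows <- vector("list", q)
  for (j in seq_len(q)) {
    kind <- (j - 1L) %% 4L
    if (kind == 0L) {
      cols[[j]] <- rbinom(n, 4L, 0.45)
      rows[[j]] <- data.frame(name = nm[j], type = "ordinal",
                              level_min = 0, level_max = 4,
                              mean = NA_real_, sd = NA_real_)
    } else if (kind == 1L) {
      cols[[j]] <- rbinom(n, 2L, 0.4)
      rows[[j]] <- data.frame(name = nm[j], type = "ordinal",
                              level_min = 0, level_max = 2,
                              mean = NA_real_, sd = NA_real_)
    } else if (kind == 2L) {
      cols[[j]] <- rbinom(n, 1L, 0.35)
      rows[[j]] <- data.frame(name = nm[j], type = "binary",
                              level_min = 0, level_max = 1,
                              mean = NA_real_, sd = NA_real_)
    } else {
      agelike <- (((j - 1L) %/% 4L) %% 2L) == 0L
      mu <- if (agelike) 42 else 25.5
      sdv <- if (agelike) 12 else 4
      cols[[j]] <- rnorm(n, mu, sdv)
      rows[[j]] <- data.frame(name = nm[j], type = "continuous",
                              level_min = NA_real_, level_max = NA_real_,
                              mean = mu, sd = sdv)
    }
  }
  x <- do.call(cbind, cols)
  colnames(x) <- nm
  attr(x, "meta") <- do.call(rbind, rows)
  x
}

#' Simulate remission outcomes under drug-specific sparse effects
#'
#' Per participant on drug `d`, the linear predictor is
#' `eta = intercepts[d] + sum_k effect_sizes[k] * (x_k - mean(x_k))` over
#' that drug's causal feature set; causal columns enter centered at their
#' cohort means so `plogis(intercepts[d])` is the arm's marginal remission
#' prevalence whatever the causal allele frequencies. In `"binary"` mode the outcome is
#' `Bernoulli(plogis(eta))`. In `"hrsd_score"` mode an integer HRSD total in
#' `[0, 52]` is produced as `clip(7 + ceiling(6 * (w - eta)), 0, 52)` with
#' `w ~ Logistic(0, 1)`, a construction that is monotone decreasing in `eta`
#' and satisfies `P(score <= 7) = plogis(eta)` exactly.
#'
#' @param features numeric feature matrix with named columns.
#' @param drug per-participant drug label matching `names(config$intercepts)`.
#' @param config a [sim_config()].
#' @return Integer vector: 0/1 remission, or an HRSD total per participant.
#' @export
simulate_outcomes <- function(features, drug, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(features)
  drug <- as.character(drug)
  miss <- setdiff(unlist(config$causal_features, use.names = FALSE),
                  colnames(features))
  if (length(miss)) {
    stop("configuration error: causal feature(s) absent from the feature matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  eta <- numeric(n)
  for (d in names(config$causal_features)) {
    rows <- drug == d
    if (!any(rows)) next
    cf <- config$causal_features[[d]]
    eta[rows] <- config$intercepts[[d]]
    if (length(cf)) {
      # causal columns enter centered at their cohort means, so the
      # intercept is the log-odds of remission at the average participant
      # and plogis(intercept) is the arm's marginal prevalence
      xc <- sweep(features[rows, cf, drop = FALSE], 2,
                  colMeans(features[, cf, drop = FALSE]))
      eta[rows] <- eta[rows] + as.vector(xc %*% config$effect_sizes[cf])
    }
  }
  set.seed(derive_seed(config$seed, 3L))
  if (config$outcome_mode == "binary") {
    out <- rbinom(n, 1L, plogis(eta))
  } else {
    w <- rlogis(n)
    out <- as.integer(pmin(pmax(7 + ceiling(6 * (w - eta)), 0), 52))
  }
  attr(out, "eta") <- eta
  out
}

#' Inject missing-completely-at-random entries
#'
#' Each eligible cell is independently set to `NA` with probability `rate`.
#' Only the named columns are eligible; callers keep outcomes, drug labels
#' and (by default) genotypes intact.
#'
#' @param x numeric matrix.
#' @param rate missingness probability in `[0, 1)`.
#' @param columns column names (or indices) eligible for masking; defaults
#'   to all columns.
#' @param seed integer seed.
#' @return `x` with masked entries set to `NA`.
#' @export
inject_missingness <- function(x, rate, columns = colnames(x), seed = 1L) {
  if (rate < 0 || rate >= 1) {
    stop("configuration error: `rate` must be in [0, 1)", call. = FALSE)
  }
  if (rate == 0 || length(columns) == 0L) return(x)
  set.seed(derive_seed(seed, 6L))
  sub <- x[, columns, drop = FALSE]
  mask <- matrix(runif(length(sub)) < rate, nrow(sub))
  sub[mask] <- NA
  x[, columns] <- sub
  x
}

#' Generate a complete synthetic randomized cohort
#'
#' Runs the full generator: genotypes, clinical variables, randomized drug
#' assignment (independent of all features, emulating trial randomization),
#' outcomes from the drug-specific logistic model, and MCAR missingness in
#' clinical columns. Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return An object of class `"remit_cohort"`: a list with elements
#'   `features` (n x p matrix: dosages then clinical columns),
#'   `feature_meta` (data frame: `name`, `kind` in genetic/clinical, `type`,
#'   `maf`, `level_min`, `level_max`), `drug` (factor), `outcome`,
#'   `outcome_type`, and `config` (the generating truth).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_participants = 60, n_snps = 20,
#'                                      n_clinical = 4, seed = 7))
#' table(cohort$drug, cohort$outcome)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- simulate_genotypes(config)
  cl <- simulate_clinical(config)
  cl_meta <- attr(cl, "meta")
  n <- config$n_participants
  drugs <- names(config$causal_features)
  set.seed(derive_seed(config$seed, 4L))
  drug <- factor(sample(drugs, n, replace = TRUE), levels = drugs)
  features <- cbind(g, cl)
  outcome <- simulate_outcomes(features, drug, config)
  eta <- attr(outcome, "eta")
  attr(outcome, "eta") <- NULL
  clin_cols <- colnames(cl)
  features <- inject_missingness(features, config$missing_rate,
                                 columns = clin_cols,
                                 seed = derive_seed(config$seed, 5L))
  meta <- data.frame(
    name = colnames(features),
    kind = c(rep("genetic", ncol(g)), rep("clinical", ncol(cl))),
    type = c(rep("dosage", ncol(g)),
             if (ncol(cl)) cl_meta$type else character(0)),
    maf = c(unname(attr(g, "maf")), rep(NA_real_, ncol(cl))),
    level_min = c(rep(0, ncol(g)),
                  if (ncol(cl)) cl_meta$level_min else numeric(0)),
    level_max = c(rep(2, ncol(g)),
                  if (ncol(cl)) cl_meta$level_max else numeric(0)),
    stringsAsFactors = FALSE)
  structure(
    list(features = features, feature_meta = meta, drug = drug,
         outcome = outcome, outcome_type = config$outcome_mode,
         eta = eta, config = config),
    class = "remit_cohort")
}

#' @export
print.remit_cohort <- function(x, ...) {
  p_gen <- sum(x$feature_meta$kind == "genetic")
  p_cli <- sum(x$feature_meta$kind == "clinical")
  cat(sprintf("Synthetic two-arm cohort: %d participants (%s), %d SNPs + %d clinical predictors\n",
              nrow(x$features),
              paste(sprintf("%s=%d", levels(x$drug), tabulate(x$drug)),
                    collapse = ", "),
              p_gen, p_cli))
  cat(sprintf("Outcome: %s; missing feature entries: %d\n",
              x$outcome_type, sum(is.na(x$features))))
  invisible(x)
}
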