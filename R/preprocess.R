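#' Genotype quality-control thresholds
#'
#' Default thresholds mirror standard pharmacogenetic practice: minor allele
#' frequency strictly greater than 0.01, per-SNP completeness of at least
#' 99%, and exclusion of variants in linkage disequilibrium with a retained
#' variant at squared correlation above 0.8.
#'
#' @param maf_min minimum minor allele frequency (exclusive bound).
#' @param completeness_min minimum non-missing fraction (inclusive bound).
#' @param ld_max maximum tolerated squared dosage correlation (exclusive
#'   bound) with any retained variant.
#' @return An object of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(maf_min = 0.01, completeness_min = 0.99,
                          ld_max = 0.8) {
  vals <- c(maf_min = maf_min, completeness_min = completeness_min,
            ld_max = ld_max)
  if (any(vals <= 0) || any(vals > 1)) {
    stop("QC thresholds must lie in (0, 1]", call. = FALSE)
  }
  structure(as.list(vals), class = "qc_thresholds")
}

#' Filter SNPs by minor allele frequency
#'
#' Empirical MAF is computed over non-missing dosages and folded to at most
#' 0.5; columns are retained when MAF is strictly greater than `maf_min`.
#' All-missing columns are excluded with a warning.
#'
#' @param genotypes dosage matrix (`{0, 1, 2}` or `NA`).
#' @param maf_min exclusive MAF bound.
#' @return Character vector of retained column names, with attribute
#'   `"maf"` giving each column's folded allele frequency.
#' @export
filter_maf <- function(genotypes, maf_min = 0.01) {
  p_alt <- colMeans(genotypes, na.rm = TRUE) / 2
  all_missing <- !is.finite(p_alt)
  if (any(all_missing)) {
    warning(sprintf("excluding %d all-missing genotype column(s)",
                    sum(all_missing)))
  }
  maf <- pmin(p_alt, 1 - p_alt)
  keep <- !all_missing & maf > maf_min
  out <- colnames(genotypes)[keep]
  attr(out, "maf") <- maf
  out
}

#' Filter SNPs by genotyping completeness
#'
#' @param genotypes dosage matrix.
#' @param completeness_min minimum non-missing fraction (inclusive).
#' @return Character vector of retained column names, with attribute
#'   `"completeness"`.
#' @export
filter_completeness <- function(genotypes, completeness_min = 0.99) {
  comp <- colMeans(!is.na(genotypes))
  out <- colnames(genotypes)[comp >= completeness_min]
  attr(out, "completeness") <- comp
  out
}

#' Prune SNPs in linkage disequilibrium
#'
#' Greedy left-to-right scan in input (positional) order: a column is
#' dropped when its squared Pearson correlation with any previously retained
#' column inside a sliding window exceeds `ld_max`. Correlations are
#' computed on mean-imputed dosages; zero-variance columns are dropped with
#' a warning (their correlation is undefined).
#'
#' @param genotypes dosage matrix in genomic order.
#' @param ld_max squared-correlation bound (exclusive).
#' @param window number of previously retained columns scanned.
#' @return List with `retained` (column names) and `dropped` (data frame
#'   with columns `feature`, `by`: the retained column that triggered
#'   exclusion, or `"zero_variance"`).
#' @export
ld_prune <- function(genotypes, ld_max = 0.8, window = 50L) {
  n <- nrow(genotypes)
  p <- ncol(genotypes)
  g <- genotypes
  # mean-fill residual missingness for the correlation scan
  if (anyNA(g)) {
    mu <- colMeans(g, na.rm = TRUE)
    for (j in which(colSums(is.na(g)) > 0)) g[is.na(g[, j]), j] <- mu[j]
  }
  mu <- colMeans(g)
  cen <- sweep(g, 2, mu)
  ss <- sqrt(colSums(cen^2))
  zero_var <- ss == 0
  if (any(zero_var)) {
    warning(sprintf("dropping %d zero-variance column(s) during LD pruning",
                    sum(zero_var)))
  }
  z <- cen
  z[, !zero_var] <- sweep(cen[, !zero_var, drop = FALSE], 2, ss[!zero_var], "/")
  retained <- integer(0)
  drop_feat <- character(0)
  drop_by <- character(0)
  for (j in seq_len(p)) {
    if (zero_var[j]) {
      drop_feat <- c(drop_feat, colnames(g)[j])
      drop_by <- c(drop_by, "zero_variance")
      next
    }
    win <- tail(retained, window)
    if (length(win)) {
      r2 <- as.vector(crossprod(z[, win, drop = FALSE], z[, j]))^2
      hit <- which(r2 > ld_max)
      if (length(hit)) {
        drop_feat <- c(drop_feat, colnames(g)[j])
        drop_by <- c(drop_by, colnames(g)[win[hit[1]]])
        next
      }
    }
    retained <- c(retained, j)
  }
  list(retained = colnames(g)[retained],
       dropped = data.frame(feature = drop_feat, by = drop_by,
                            stringsAsFactors = FALSE))
}

fill_mode <- function(x) {
  obs <- x[!is.na(x)]
  tab <- table(obs)
  # ties broken toward the smaller value (names sort in value order)
  as.numeric(names(tab)[which.max(tab)])
}

#' Impute missing values with bagged trees
#'
#' For every column containing missing entries, fits an ensemble of
#' `n_trees` CART trees (rpart) on bootstrap resamples of the rows observed
#' in that column, using all other columns as predictors (their own missing
#' entries mean-/mode-filled for the fit). Missing cells are predicted by
#' the ensemble mean for continuous columns and by plurality vote (ties
#' toward the smaller value) for ordinal/binary columns. Deterministic given
#' `seed`; observed cells are never altered.
#'
#' @param x numeric feature matrix.
#' @param meta feature metadata data frame with columns `name` and `type`
#'   (`continuous` columns use regression trees; anything else is treated as
#'   categorical).
#' @param n_trees ensemble size per column.
#' @param seed integer seed.
#' @return Completed matrix with attribute `"imputed_mask"`, a logical
#'   matrix marking the cells that were filled.
#' @export
impute_bagged_trees <- function(x, meta, n_trees = 25L, seed = 1L) {
  mask <- is.na(x)
  if (!any(mask)) {
    attr(x, "imputed_mask") <- mask
    return(x)
  }
  types <- setNames(meta$type, meta$name)
  # mean/mode-filled copy used as the predictor pool
  filled <- x
  for (j in which(colSums(mask) > 0L)) {
    if (all(mask[, j])) {
      stop(sprintf("cannot impute column `%s`: no observed values",
                   colnames(x)[j]), call. = FALSE)
    }
    tp <- types[colnames(x)[j]]
    filled[mask[, j], j] <- if (identical(unname(tp), "continuous")) {
      mean(x[, j], na.rm = TRUE)
    } else {
      fill_mode(x[, j])
    }
  }
  out <- x
  for (j in which(colSums(mask) > 0L)) {
    cn <- colnames(x)[j]
    obs <- which(!mask[, j])
    mis <- which(mask[, j])
    categorical <- !identical(unname(types[cn]), "continuous")
    df <- as.data.frame(filled[, setdiff(colnames(x), cn), drop = FALSE])
    yobs <- x[obs, j]
    set.seed(derive_seed(seed, 10L + j))
    if (categorical) {
      lev <- sort(unique(yobs))
      votes <- matrix(0L, length(mis), length(lev))
      for (t in seq_len(n_trees)) {
        idx <- sample(obs, replace = TRUE)
        fit <- rpart::rpart(y ~ ., data = cbind(df[idx, , drop = FALSE],
                                                y = factor(x[idx, j], levels = lev)),
                            method = "class")
        pred <- predict(fit, df[mis, , drop = FALSE], type = "class")
        votes <- votes + outer(as.character(pred), as.character(lev), `==`)
      }
      out[mis, j] <- lev[apply(votes, 1, which.max)]
    } else {
      acc <- numeric(length(mis))
      for (t in seq_len(n_trees)) {
        idx <- sample(obs, replace = TRUE)
        fit <- rpart::rpart(y ~ ., data = cbind(df[idx, , drop = FALSE],
                                                y = x[idx, j]),
                            method = "anova")
        acc <- acc + predict(fit, df[mis, , drop = FALSE])
      }
      out[mis, j] <- acc / n_trees
    }
  }
  attr(out, "imputed_mask") <- mask
  out
}

snap_to_admissible <- function(v, admissible) {
  # nearest admissible value; exact ties resolved toward the smaller value
  vapply(v, function(u) admissible[which.min(abs(admissible - u))], numeric(1))
}

#' Round imputed categorical values to admissible levels
#'
#' Replaces imputed values in ordinal/binary (and dosage) columns by the
#' nearest admissible value, with exact ties broken toward the smaller
#' value. Observed cells are untouched: only cells flagged in `mask` are
#' rounded (with `mask = NULL`, every cell of a categorical column is
#' snapped).
#'
#' @param x numeric feature matrix.
#' @param meta metadata with `name`, `type`, `level_min`, `level_max`.
#' @param mask logical matrix marking imputed cells (e.g. the
#'   `"imputed_mask"` attribute of [impute_bagged_trees()]).
#' @return The rounded matrix.
#' @export
round_categorical <- function(x, meta, mask = NULL) {
  cat_rows <- meta$type %in% c("ordinal", "binary", "dosage")
  for (i in which(cat_rows)) {
    cn <- meta$name[i]
    if (!cn %in% colnames(x)) next
    if (!is.finite(meta$level_min[i]) || !is.finite(meta$level_max[i]) ||
        meta$level_min[i] > meta$level_max[i]) {
      stop(sprintf("configuration error: empty admissible set for `%s`", cn),
           call. = FALSE)
    }
    adm <- seq(meta$level_min[i], meta$level_max[i])
    cells <- if (is.null(mask)) rep(TRUE, nrow(x)) else mask[, cn]
    cells <- cells & !is.na(x[, cn])
    if (any(cells)) x[cells, cn] <- snap_to_admissible(x[cells, cn], adm)
  }
  x
}

#' Derive binary remission from an HRSD-17 total
#'
#' Remission is an end-of-treatment score of 7 points or less on the
#' 17-item Hamilton Rating Scale for Depression.
#'
#' @param hrsd_total integer score(s) in `[0, 52]`.
#' @return Integer vector: 1 = remitter, 0 = non-remitter.
#' @export
derive_remission <- function(hrsd_total) {
  if (anyNA(hrsd_total) || any(hrsd_total < 0 | hrsd_total > 52) ||
      any(hrsd_total != round(hrsd_total))) {
    stop("HRSD totals must be integers in [0, 52]", call. = FALSE)
  }
  as.integer(hrsd_total <= 7)
}

#' Split a cohort into training and validation partitions
#'
#' Random split with training size `round(n * train_fraction)` (half-up),
#' stratified by outcome-by-drug cell so that each partition's cell
#' proportions differ from the whole cohort by at most one participant per
#' stratum (largest-remainder allocation). Strata with fewer than two
#' members are assigned wholly to training with a warning. Deterministic
#' given `seed`.
#'
#' @param outcome per-participant outcome (binary or otherwise discrete).
#' @param drug optional per-participant drug label; crossed with the
#'   outcome when `stratify = TRUE`.
#' @param train_fraction training proportion in `(0, 1)`; 0.65 reproduces
#'   the canonical 280/150 division of a 430-participant cohort.
#' @param seed integer seed.
#' @param stratify stratify by outcome (by drug)? If `FALSE`, a simple
#'   random split.
#' @return List with sorted integer index vectors `train` and `validation`,
#'   disjoint and exhaustive.
#' @export
split_train_validation <- function(outcome, drug = NULL, train_fraction = 0.65,
                                   seed = 1L, stratify = TRUE) {
  n <- length(outcome)
  if (n < 1L) stop("cohort is empty", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  target <- floor(n * train_fraction + 0.5)
  strata <- if (stratify) {
    if (is.null(drug)) factor(outcome) else interaction(outcome, drug, drop = TRUE)
  } else {
    factor(rep(1L, n))
  }
  set.seed(derive_seed(seed, 20L))
  members <- split(seq_len(n), strata)
  sizes <- lengths(members)
  small <- sizes < 2L
  if (any(small)) {
    warning(sprintf("%d stratum(s) with fewer than 2 members assigned wholly to training",
                    sum(small)))
  }
  train <- unlist(members[small], use.names = FALSE)
  target_rest <- max(target - length(train), 0L)
  rest <- members[!small]
  if (length(rest)) {
    exact <- lengths(rest) * train_fraction
    base <- pmin(floor(exact), lengths(rest))
    rem <- target_rest - sum(base)
    if (rem > 0) {
      frac <- exact - floor(exact)
      bump <- order(frac, decreasing = TRUE)
      bump <- bump[seq_len(min(rem, length(bump)))]
      base[bump] <- pmin(base[bump] + 1L, lengths(rest)[bump])
    } else if (rem < 0) {
      shrink <- order(exact - floor(exact))
      shrink <- shrink[seq_len(min(-rem, length(shrink)))]
      base[shrink] <- pmax(base[shrink] - 1L, 0L)
    }
    for (k in seq_along(rest)) {
      idx <- rest[[k]]
      take <- if (base[k] >= length(idx)) idx else sample(idx, base[k])
      train <- c(train, take)
    }
  }
  train <- sort(unique(train))
  list(train = train, validation = setdiff(seq_len(n), train))
}

fill_genotype_mode <- function(g) {
  for (j in which(colSums(is.na(g)) > 0L)) {
    g[is.na(g[, j]), j] <- fill_mode(g[, j])
  }
  g
}

#' Prepare a cohort for modelling
#'
#' Applies the full predictor-preparation sequence: genotype filters (MAF,
#' completeness, LD pruning), column-mode completion of residual genotype
#' missingness, bagged-tree imputation of clinical predictors with
#' categorical rounding of the imputed cells, and derivation of binary
#' remission when the cohort carries HRSD totals.
#'
#' @param cohort a `"remit_cohort"`.
#' @param qc a [qc_thresholds()].
#' @param n_trees bagged-tree ensemble size.
#' @param ld_window LD-pruning window (number of retained columns scanned).
#' @param seed integer seed for the imputation ensembles.
#' @return The cohort with filtered, completed features, binary outcome, and
#'   attribute `"qc_log"` (dropped columns per filter and imputation counts).
#' @export
preprocess_cohort <- function(cohort, qc = qc_thresholds(), n_trees = 25L,
                              ld_window = 50L, seed = 1L) {
  stopifnot(inherits(cohort, "remit_cohort"))
  meta <- cohort$feature_meta
  gen <- meta$name[meta$kind == "genetic"]
  cli <- meta$name[meta$kind == "clinical"]
  g <- cohort$features[, gen, drop = FALSE]

  keep_maf <- filter_maf(g, qc$maf_min)
  g <- g[, keep_maf, drop = FALSE]
  keep_comp <- filter_completeness(g, qc$completeness_min)
  g <- g[, keep_comp, drop = FALSE]
  pruned <- ld_prune(g, qc$ld_max, window = ld_window)
  g <- g[, pruned$retained, drop = FALSE]
  g <- fill_genotype_mode(g)

  cl <- cohort$features[, cli, drop = FALSE]
  n_missing <- sum(is.na(cl))
  if (n_missing > 0L) {
    cl <- impute_bagged_trees(cl, meta[meta$kind == "clinical", , drop = FALSE],
                              n_trees = n_trees, seed = seed)
    cl <- round_categorical(cl, meta[meta$kind == "clinical", , drop = FALSE],
                            mask = attr(cl, "imputed_mask"))
  }

  outcome <- cohort$outcome
  hrsd_total <- NULL
  if (cohort$outcome_type == "hrsd_score") {
    hrsd_total <- outcome
    outcome <- derive_remission(outcome)
  }

  features <- cbind(as.matrix(g), as.matrix(cl))
  meta_out <- meta[match(colnames(features), meta$name), , drop = FALSE]
  rownames(meta_out) <- NULL
  out <- cohort
  out$features <- features
  out$feature_meta <- meta_out
  out$outcome <- outcome
  out$outcome_type <- "binary"
  out$hrsd_total <- hrsd_total
  attr(out, "qc_log") <- list(
    maf_dropped = setdiff(gen, keep_maf),
    completeness_dropped = setdiff(keep_maf, keep_comp),
    ld_dropped = pruned$dropped,
    n_clinical_imputed = n_missing)
  out
}
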