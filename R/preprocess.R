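#' Recode reserved survey sentinel codes
#'
#' Applies the standard sentinel semantics to every variable: -3, -7, -8
#' and -9 ("no data in round", "refused", "do not know", "not
#' ascertained") become missing; -1 ("inapplicable") becomes an explicit
#' extra level for categorical variables and missing for continuous ones;
#' -2 ("same as previous round") is replaced by the paired prior-round
#' variable's value when the codebook names one, else becomes missing.
#' Negative integer codes in categorical columns that are not in the
#' reserved set trigger a warning and are left untouched.
#'
#' @param cohort a `survey_cohort`.
#' @return the cohort with recoded `values` (NA for missing), updated
#'   `meta` (level counts grown where an inapplicable level was added) and
#'   a `recode_report` data frame attached.
#' @export
recode_reserved <- function(cohort) {
  values <- cohort$values
  meta <- cohort$meta
  missing_codes <- c(-3, -7, -8, -9)
  report <- data.frame(name = meta$name, n_missing_coded = 0L,
                       n_inapplicable = 0L, n_carried = 0L,
                       stringsAsFactors = FALSE)

  for (j in seq_len(ncol(values))) {
    x <- values[, j]
    kind <- meta$kind[j]
    hit_missing <- x %in% missing_codes
    report$n_missing_coded[j] <- sum(hit_missing)
    x[hit_missing] <- NA_real_

    hit_carry <- !is.na(x) & x == -2
    if (any(hit_carry)) {
      partner <- if ("prior_var" %in% names(meta)) meta$prior_var[j] else NA
      if (!is.na(partner) && partner %in% colnames(values)) {
        x[hit_carry] <- values[hit_carry, partner]
      } else {
        x[hit_carry] <- NA_real_
      }
      report$n_carried[j] <- sum(hit_carry)
    }

    hit_inap <- !is.na(x) & x == -1
    if (any(hit_inap)) {
      if (kind %in% c("nominal", "ordinal")) {
        # explicit INAPPLICABLE level appended after the observed levels
        new_level <- meta$n_levels[j] + 1L
        x[hit_inap] <- new_level
        meta$n_levels[j] <- new_level
      } else {
        x[hit_inap] <- NA_real_
      }
      report$n_inapplicable[j] <- sum(hit_inap)
    }

    if (kind %in% c("nominal", "ordinal")) {
      stray <- !is.na(x) & x < 0
      if (any(stray)) {
        warning(sprintf("variable %s: %d negative values not in the reserved-code set were left untouched",
                        meta$name[j], sum(stray)))
      }
    }
    values[, j] <- x
  }

  cohort$values <- values
  cohort$meta <- meta
  cohort$recode_report <- report
  cohort
}

#' Skewness-gated log transform
#'
#' Log-transforms a continuous vector if and only if doing so reduces the
#' absolute sample skewness. For vectors with non-positive values the
#' transform is `log(x + shift)` with `shift = 1 - min(x)`; skewness is
#' the unweighted third standardized moment (survey weights ignored).
#'
#' @param x continuous vector, possibly with NA.
#' @return list with `transformed` (logical), `values` (transformed or
#'   original), `shift`, `skew_before`, `skew_after`, `note`.
#' @export
#' @examples
#' choose_log_transform(rlnorm(100))$transformed  # TRUE: lognormal is skewed
choose_log_transform <- function(x) {
  obs <- x[!is.na(x)]
  if (length(obs) < 3L) {
    stop("need at least 3 non-missing values to assess skewness")
  }
  s0 <- sample_skewness(x)
  if (is.na(s0)) {
    return(list(transformed = FALSE, values = x, shift = 0,
                skew_before = NA_real_, skew_after = NA_real_,
                note = "constant vector: skewness undefined, no transform"))
  }
  shift <- if (min(obs) <= 0) 1 - min(obs) else 0
  lx <- log(x + shift)
  s1 <- sample_skewness(lx)
  if (!is.na(s1) && abs(s1) < abs(s0)) {
    list(transformed = TRUE, values = lx, shift = shift,
         skew_before = s0, skew_after = s1, note = "")
  } else {
    list(transformed = FALSE, values = x, shift = shift,
         skew_before = s0, skew_after = s1, note = "")
  }
}

#' Spearman rank-correlation redundancy filter
#'
#' Removes near-rank-identical variables. Variables are scanned in column
#' order; a variable is dropped iff its absolute Spearman correlation with
#' an earlier *retained* variable exceeds `threshold`. Correlations use
#' pairwise-complete observations (subjects with a missing value in either
#' variable of a pair are dropped for that pair); a pair with fewer than 3
#' complete observations is treated as uncorrelated with a warning.
#'
#' @param values numeric matrix (categoricals as integer codes).
#' @param threshold redundancy cutoff on |rho| (default 0.9).
#' @return list with `retained` (column indices, original order),
#'   `dropped` (data frame: column, partner, rho), `rho` (the full
#'   Spearman matrix).
#' @export
spearman_redundancy_filter <- function(values, threshold = 0.9) {
  p <- ncol(values)
  if (p < 2L) return(list(retained = seq_len(p),
                          dropped = data.frame(), rho = NULL))
  rho <- suppressWarnings(
    stats::cor(values, method = "spearman", use = "pairwise.complete.obs"))
  n_complete <- crossprod(!is.na(values))
  few <- n_complete < 3L
  diag(few) <- FALSE
  if (any(few)) {
    warning("some variable pairs have fewer than 3 complete observations; their correlation is treated as 0")
  }
  rho[few] <- 0
  rho[is.na(rho)] <- 0  # zero-variance columns correlate with nothing

  retained <- integer(0)
  dropped <- list()
  for (j in seq_len(p)) {
    if (length(retained) == 0L) {
      retained <- j
      next
    }
    r_prev <- abs(rho[j, retained])
    if (any(r_prev > threshold)) {
      partner <- retained[which.max(r_prev)]
      dropped[[length(dropped) + 1L]] <-
        data.frame(column = j, partner = partner, rho = rho[j, partner])
    } else {
      retained <- c(retained, j)
    }
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(column = integer(0), partner = integer(0), rho = numeric(0))
  list(retained = retained, dropped = dropped, rho = rho)
}

#' Chained-equation imputation
#'
#' Single-imputation sweeps in the chained-equations style: after a
#' mean/mode initial fill, each variable with missing entries is visited
#' in turn and its missing cells replaced by the prediction of a model of
#' that variable on all others (linear regression for continuous
#' variables; a most-probable-class linear classifier over level
#' indicators for categoricals), repeated for `n_iterations` sweeps.
#' Deterministic given the seed.
#'
#' @param values numeric matrix with NA for missing.
#' @param kinds character vector per column: "continuous", "ordinal" or
#'   "nominal".
#' @param n_iterations number of sweeps (default 5).
#' @param seed integer seed.
#' @return completed numeric matrix (no NA).
#' @export
impute_chained <- function(values, kinds, n_iterations = 5L, seed = 1L) {
  p <- ncol(values)
  stopifnot(length(kinds) == p)
  miss <- is.na(values)
  all_missing <- colSums(!miss) == 0L
  if (any(all_missing)) {
    stop("variable(s) fully missing, cannot impute: ",
         paste(colnames(values)[all_missing], collapse = ", "))
  }
  if (!any(miss)) return(values)
  set.seed(seed)

  filled <- values
  for (j in seq_len(p)) {
    mj <- miss[, j]
    if (!any(mj)) next
    obs <- values[!mj, j]
    filled[mj, j] <- if (kinds[j] == "continuous") mean(obs) else
      as.numeric(names(which.max(table(obs))))
  }

  targets <- which(colSums(miss) > 0L)
  for (it in seq_len(n_iterations)) {
    for (j in targets) {
      mj <- miss[, j]
      X <- cbind(1, filled[, -j, drop = FALSE])
      if (kinds[j] == "continuous") {
        fit <- stats::lm.fit(X[!mj, , drop = FALSE], filled[!mj, j])
        beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
        filled[mj, j] <- X[mj, , drop = FALSE] %*% beta
      } else {
        lv <- sort(unique(values[!mj, j]))
        if (length(lv) == 1L) { filled[mj, j] <- lv; next }
        # linear-probability score per level; impute the argmax level
        Y <- outer(filled[!mj, j], lv, `==`) + 0
        fit <- stats::lm.fit(X[!mj, , drop = FALSE], Y)
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        scores <- X[mj, , drop = FALSE] %*% beta
        filled[mj, j] <- lv[max.col(scores, ties.method = "first")]
      }
    }
  }
  filled
}

#' Expand nominal variables into reference-coded indicators
#'
#' Each nominal variable with k observed levels becomes k-1 binary
#' indicator columns (the first level in codebook order is the reference).
#' Ordinal and continuous variables pass through unchanged as numeric
#' columns. A nominal with a single observed level contributes no columns
#' (with a warning).
#'
#' @param values complete numeric matrix.
#' @param kinds per-column kind as in [impute_chained()].
#' @return list with `expanded` (numeric matrix), `map` (data frame:
#'   out_column, source, level; level NA for pass-through columns).
#' @export
expand_nominal <- function(values, kinds) {
  p <- ncol(values)
  nm <- colnames(values)
  if (is.null(nm)) nm <- paste0("V", seq_len(p))
  out <- list()
  map <- list()
  for (j in seq_len(p)) {
    if (kinds[j] != "nominal") {
      out[[length(out) + 1L]] <- values[, j]
      names(out)[length(out)] <- nm[j]
      map[[length(map) + 1L]] <- data.frame(out_column = nm[j],
                                            source = nm[j],
                                            level = NA_real_)
      next
    }
    lv <- sort(unique(values[, j]))
    if (length(lv) < 2L) {
      warning(sprintf("nominal variable %s has a single observed level; no indicators created", nm[j]))
      next
    }
    for (l in lv[-1L]) {  # first level = reference
      cname <- sprintf("%s.%g", nm[j], l)
      out[[length(out) + 1L]] <- as.numeric(values[, j] == l)
      names(out)[length(out)] <- cname
      map[[length(map) + 1L]] <- data.frame(out_column = cname,
                                            source = nm[j], level = l)
    }
  }
  expanded <- do.call(cbind, out)
  list(expanded = expanded, map = do.call(rbind, map))
}

#' Survey-weighted centering and scaling
#'
#' Standardizes each column to weighted mean 0 and weighted variance 1,
#' using probability weights normalized to sum to one. Columns with
#' (weighted) zero variance are excluded with a warning and recorded.
#'
#' @param values complete numeric matrix.
#' @param weights positive survey weights.
#' @return list with `x` (standardized matrix), `means`, `scales`
#'   (for the retained columns) and `dropped` (names of zero-variance
#'   columns).
#' @export
center_scale_weighted <- function(values, weights) {
  stopifnot(nrow(values) == length(weights))
  if (all(weights == 0)) stop("all weights are zero")
  if (any(weights < 0)) stop("weights must be positive")
  wn <- weights / sum(weights)
  m <- colSums(wn * values)
  ctr <- sweep(values, 2, m)
  v <- colSums(wn * ctr^2)
  keep <- v > 1e-12
  if (!all(keep)) {
    warning("zero-variance column(s) excluded from standardization: ",
            paste(colnames(values)[!keep], collapse = ", "))
  }
  s <- sqrt(v[keep])
  x <- sweep(ctr[, keep, drop = FALSE], 2, s, `/`)
  list(x = x, means = m[keep], scales = s,
       dropped = colnames(values)[!keep])
}

#' Run the full preprocessing pipeline on a cohort
#'
#' Reserved-code recoding, skewness-gated log transforms of continuous
#' variables, Spearman redundancy filtering (|rho| > `rho` against an
#' earlier retained variable), chained-equation imputation, reference
#' coding of nominals, and survey-weighted standardization — producing
#' the matrix on which the weighted PCA runs.
#'
#' @param cohort a `survey_cohort`.
#' @param rho redundancy threshold (default 0.9).
#' @param n_iterations imputation sweeps.
#' @param seed seed for the imputation stage.
#' @return list of class `preprocess_result`: `x` (standardized matrix),
#'   `weights`, `means`, `scales`, `map` (expansion provenance),
#'   `report` (per-variable log/drop/missingness bookkeeping),
#'   `retained` (post-filter variable names), `kinds`.
#' @export
preprocess_cohort <- function(cohort, rho = 0.9, n_iterations = 5L,
                              seed = 1L) {
  coh <- recode_reserved(cohort)
  values <- coh$values
  meta <- coh$meta

  log_flags <- logical(ncol(values))
  skew_before <- skew_after <- rep(NA_real_, ncol(values))
  for (j in which(meta$kind == "continuous")) {
    if (sum(!is.na(values[, j])) < 3L) next
    lt <- choose_log_transform(values[, j])
    values[, j] <- lt$values
    log_flags[j] <- lt$transformed
    skew_before[j] <- lt$skew_before
    skew_after[j] <- lt$skew_after
  }

  filt <- spearman_redundancy_filter(values, threshold = rho)
  retained <- filt$retained
  vals_f <- values[, retained, drop = FALSE]
  kinds_f <- meta$kind[retained]

  complete <- impute_chained(vals_f, kinds_f, n_iterations = n_iterations,
                             seed = seed)

  exp <- expand_nominal(complete, kinds_f)
  std <- center_scale_weighted(exp$expanded, cohort$subjects$weight)

  report <- data.frame(
    name = meta$name,
    kind = meta$kind,
    log_transformed = log_flags,
    skew_before = skew_before,
    skew_after = skew_after,
    missing_fraction = colMeans(is.na(values)),
    retained = seq_len(ncol(values)) %in% retained,
    stringsAsFactors = FALSE)
  report$redundant_partner <- NA_character_
  if (nrow(filt$dropped)) {
    report$redundant_partner[filt$dropped$column] <-
      meta$name[filt$dropped$partner]
  }

  structure(list(x = std$x, weights = cohort$subjects$weight,
                 means = std$means, scales = std$scales,
                 map = exp$map, report = report,
                 retained = meta$name[retained], kinds = kinds_f,
                 dropped_constant = std$dropped),
            class = "preprocess_result")
}
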