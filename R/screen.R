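#' Expand a cohort into a quarterly person-period table
#'
#' Discrete-time survival setup: each subject contributes one row per
#' quarter survived into the second year. A survivor has 4 rows, all
#' `died = 0`; a subject dying in quarter q has exactly q rows with
#' `died = 1` only on the last. Covariates and design variables are
#' copied to every row.
#'
#' @param cohort a `survey_cohort` (or any list with a `subjects` data
#'   frame holding `death_quarter` in `{1..4, NA}`).
#' @return data frame of class `person_period` with columns `subject_row`
#'   (row index into the cohort), `id`, `quarter` (factor Jan-Mar ...
#'   Oct-Dec), `died`, `weight`, `stratum`, `psu`, `age`, `sex`, `race`.
#' @export
expand_person_periods <- function(cohort) {
  s <- cohort$subjects
  dq <- s$death_quarter
  bad <- !is.na(dq) & !(dq %in% 1:4)
  if (any(bad)) {
    stop("death_quarter outside {1..4, NA} for subject(s): ",
         paste(utils::head(s$id[bad]), collapse = ", "))
  }
  n_rows <- ifelse(is.na(dq), 4L, dq)
  subject_row <- rep(seq_len(nrow(s)), n_rows)
  quarter <- sequence(n_rows)
  died <- as.integer(!is.na(dq[subject_row]) & quarter == dq[subject_row])
  out <- data.frame(
    subject_row = subject_row,
    id = s$id[subject_row],
    quarter = factor(quarter, levels = 1:4,
                     labels = c("Jan-Mar", "Apr-Jun", "Jul-Sep", "Oct-Dec")),
    died = died,
    weight = s$weight[subject_row],
    stratum = s$stratum[subject_row],
    psu = s$psu[subject_row],
    age = s$age[subject_row],
    sex = s$sex[subject_row],
    race = s$race[subject_row])
  class(out) <- c("person_period", "data.frame")
  out
}

#' Fit a discrete-time event-history model for one index
#'
#' Weighted logistic (discrete-time hazard) model of quarterly death on
#' the index: `died ~ 0 + quarter + index + quarter:index`, giving one
#' intercept per quarter, the index main effect and index-by-quarter
#' interactions. The adjusted variant adds age (years), sex and race
#' (reference white). Estimation is by survey-weighted maximum likelihood
#' (weights normalized to mean 1); the index p-value is the two-sided
#' Wald test on the main effect alone (in this parameterization, the
#' first-quarter slope).
#'
#' Two variance estimators are available. The default, `"model"`, is a
#' weight-aware model-assisted sandwich whose meat is the expected score
#' variance `sum_i w_i^2 mu_i (1 - mu_i) x_i x_i'`: it accounts exactly
#' for the variance inflation caused by unequal survey weights, reduces
#' to the classical model-based covariance under equal weights, and
#' remains stable when deaths are rare. `"cluster"` is the empirical
#' PSU-clustered sandwich; it additionally captures within-PSU outcome
#' correlation but its meat is estimated from the event rows, which
#' makes it strongly anticonservative when only a handful of deaths
#' inform the coefficient (see the package vignette for measured sizes).
#'
#' Fits with a zero-variance index, an aliased or runaway index
#' coefficient (separation guard |coef| > 15 on any index term) are
#' flagged non-converged with absent p-values; separation confined to
#' nuisance covariate levels (e.g. a race category with no deaths) does
#' not invalidate the index test and is tolerated.
#'
#' @param ppt a `person_period` table.
#' @param index_values per-subject index values aligned with the cohort
#'   rows that produced `ppt`.
#' @param adjusted add age/sex/race covariates?
#' @param variance `"model"` (weight-aware expected-meat sandwich,
#'   default) or `"cluster"` (empirical PSU-clustered sandwich).
#' @return list of class `screen_result`: `model` ("unadjusted" /
#'   "adjusted"), `beta_index`, `se_index`, `p_index`, `interactions`
#'   (data frame term/beta/se/p), `quarter_intercepts`,
#'   `residual_deviance`, `converged`.
#' @export
fit_discrete_time <- function(ppt, index_values, adjusted = FALSE,
                              variance = c("model", "cluster")) {
  variance <- match.arg(variance)
  model_name <- if (adjusted) "adjusted" else "unadjusted"
  idx <- index_values[ppt$subject_row]
  not_ok <- function() {
    structure(list(model = model_name, beta_index = NA_real_,
                   se_index = NA_real_, p_index = NA_real_,
                   interactions = NULL, quarter_intercepts = NULL,
                   residual_deviance = NA_real_, converged = FALSE),
              class = "screen_result")
  }
  if (nrow(ppt) == 0L || stats::var(idx) <= 0) return(not_ok())

  df <- data.frame(died = ppt$died, quarter = ppt$quarter, idx = idx,
                   w = ppt$weight / mean(ppt$weight))
  if (adjusted) {
    df$age <- ppt$age
    df$sex <- ppt$sex
    df$race <- stats::relevel(factor(ppt$race), ref = "white")
    form <- died ~ 0 + quarter + idx + quarter:idx + age + sex + race
  } else {
    form <- died ~ 0 + quarter + idx + quarter:idx
  }
  fit <- tryCatch(
    suppressWarnings(stats::glm(form, family = stats::quasibinomial(),
                                data = df, weights = w)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(not_ok())
  cf <- stats::coef(fit)
  # separation guard on the screened quantity: the index main effect and
  # its quarter interactions (plus the quarter intercepts the test
  # conditions on); runaway nuisance covariate levels are tolerated
  core <- grepl("^quarter|idx", names(cf))
  if (anyNA(cf[core]) || max(abs(cf[grepl("idx", names(cf))])) > 15) {
    return(not_ok())
  }

  keep <- !is.na(cf)
  X <- stats::model.matrix(fit)[, keep, drop = FALSE]
  mu <- stats::fitted(fit)
  wb <- df$w * mu * (1 - mu)
  bread <- tryCatch(solve(crossprod(X, wb * X)), error = function(e) NULL)
  if (is.null(bread)) return(not_ok())
  meat <- if (variance == "cluster" && length(unique(ppt$psu)) > 1L) {
    # empirical PSU-clustered meat (HC0 with G/(G-1) correction)
    S <- rowsum((df$w * (df$died - mu)) * X, ppt$psu)
    G <- nrow(S)
    crossprod(S) * G / (G - 1)
  } else {
    # expected score variance: exact for unequal weights, stable under
    # rare events; equals the Fisher information at equal weights
    crossprod(X, (df$w^2 * mu * (1 - mu)) * X)
  }
  vc <- bread %*% meat %*% bread
  se <- rep(NA_real_, length(cf))
  names(se) <- names(cf)
  se[keep] <- sqrt(pmax(diag(vc), 0))
  z <- cf / se
  pv <- 2 * stats::pnorm(-abs(z))

  int_terms <- grep("^quarter.*:idx$", names(cf), value = TRUE)
  q_terms <- grep("^quarter[^:]*$", names(cf), value = TRUE)
  structure(list(
    model = model_name,
    beta_index = unname(cf["idx"]),
    se_index = unname(se["idx"]),
    p_index = unname(pv["idx"]),
    interactions = data.frame(term = int_terms,
                              beta = unname(cf[int_terms]),
                              se = unname(se[int_terms]),
                              p = unname(pv[int_terms]),
                              row.names = NULL),
    quarter_intercepts = cf[q_terms],
    residual_deviance = fit$deviance,
    converged = TRUE), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("screen_result (%s): did not converge\n", x$model))
    return(invisible(x))
  }
  cat(sprintf("screen_result (%s): beta = %.4f (SE %.4f), p = %.3g, deviance = %.1f\n",
              x$model, x$beta_index, x$se_index, x$p_index,
              x$residual_deviance))
  invisible(x)
}

#' Screen every cumulative index against mortality
#'
#' For each component the indices are evaluated as a running cumulative
#' sum over the loading-ordered variables (memory stays at one vector per
#' component), and each index is fitted unadjusted and, optionally,
#' adjusted. Failures are recorded as non-converged rows, never raised.
#'
#' @param cohort a `survey_cohort`.
#' @param model a fitted `weighted_pca`.
#' @param x the standardized matrix the PCA was fitted on.
#' @param alpha significance threshold (default 0.05, no multiplicity
#'   correction).
#' @param adjusted one of "both", "unadjusted", "adjusted".
#' @param variance variance estimator passed to [fit_discrete_time()].
#' @param verbose print one progress line per component?
#' @return data frame of class `screen_table`, one row per (pc, n, model):
#'   `pc`, `n`, `model`, `beta`, `se`, `p`, `deviance`, `converged`,
#'   `significant`; attribute `"alpha"`.
#' @export
screen_all <- function(cohort, model, x, alpha = 0.05,
                       adjusted = c("both", "unadjusted", "adjusted"),
                       variance = c("model", "cluster"),
                       verbose = FALSE) {
  adjusted <- match.arg(adjusted)
  variance <- match.arg(variance)
  fit_unadj <- adjusted %in% c("both", "unadjusted")
  fit_adj <- adjusted %in% c("both", "adjusted")
  ppt <- expand_person_periods(cohort)
  N <- model$n_variables
  n_models <- fit_unadj + fit_adj
  total <- N * N * n_models

  pc_v <- integer(total); n_v <- integer(total)
  mod_v <- character(total); beta_v <- se_v <- p_v <- dev_v <-
    rep(NA_real_, total); conv_v <- logical(total)
  k <- 0L
  for (pc in seq_len(N)) {
    ord <- rank_variables_by_loading(model, pc)
    cum <- numeric(nrow(x))
    for (n in seq_len(N)) {
      cum <- cum + x[, ord[n]] * model$loadings[ord[n], pc]
      for (adj in c(FALSE, TRUE)[c(fit_unadj, fit_adj)]) {
        res <- fit_discrete_time(ppt, cum, adjusted = adj,
                                 variance = variance)
        k <- k + 1L
        pc_v[k] <- pc; n_v[k] <- n; mod_v[k] <- res$model
        beta_v[k] <- res$beta_index; se_v[k] <- res$se_index
        p_v[k] <- res$p_index; dev_v[k] <- res$residual_deviance
        conv_v[k] <- res$converged
      }
    }
    if (verbose) {
      message(sprintf("screened PC %d/%d (%d fits so far)", pc, N, k))
    }
  }
  out <- data.frame(pc = pc_v, n = n_v, model = mod_v, beta = beta_v,
                    se = se_v, p = p_v, deviance = dev_v,
                    converged = conv_v)
  # non-converged fits count as not significant
  out$significant <- out$converged & !is.na(out$p) & out$p < alpha
  attr(out, "alpha") <- alpha
  class(out) <- c("screen_table", "data.frame")
  out
}

#' Survey-weighted Kaplan-Meier curves by month
#'
#' Product-limit survival estimates over the 12 months of the second
#' year, weighted by the survey weights, optionally split by a grouping
#' variable. Subjects with a known death quarter but no death month are
#' assigned the mid-quarter month. Survivors are censored at month 12.
#'
#' @param cohort a `survey_cohort`.
#' @param group_by optional name of a `subjects` column (e.g. "sex",
#'   "race") to stratify by.
#' @return a [survival::survfit] object.
#' @export
weighted_km <- function(cohort, group_by = NULL) {
  s <- cohort$subjects
  event <- as.integer(!is.na(s$death_quarter))
  month <- s$death_month
  fill <- event == 1L & is.na(month)
  month[fill] <- (s$death_quarter[fill] - 1L) * 3L + 2L  # mid-quarter
  time <- ifelse(event == 1L, month, 12L)
  df <- data.frame(time = time, event = event, w = s$weight)
  if (is.null(group_by)) {
    survival::survfit(survival::Surv(time, event) ~ 1, data = df,
                      weights = w)
  } else {
    g0 <- s[[group_by]]
    if (is.null(g0)) stop("no such subject column: ", group_by)
    g <- droplevels(factor(g0))
    all_levels <- if (is.factor(g0)) levels(g0) else unique(g0)
    empty <- setdiff(all_levels, levels(g))
    if (length(empty)) {
      warning("empty group(s) dropped: ", paste(empty, collapse = ", "))
    }
    df$group <- g
    survival::survfit(survival::Surv(time, event) ~ group, data = df,
                      weights = w)
  }
}
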