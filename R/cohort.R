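#' Configuration for a synthetic survey cohort
#'
#' Describes a two-year-panel-style survey cohort: a mixed-type variable
#' matrix driven by one latent risk factor, complex-sampling design
#' variables (weights, strata, PSUs), demographics, and a second-year
#' mortality outcome recorded by quarter of death.
#'
#' Defaults emulate the structure of a pooled national expenditure-survey
#' panel: tens of thousands of subjects; a post-curation variable mix of
#' 15 continuous, 3 ordinal and 68 nominal variables whose level counts
#' sum so that reference-coded expansion yields 184 indicator columns;
#' engineered redundancy (monotone copies); sentinel reserved codes for
#' inapplicability and flavours of missingness; lognormal-skewed sampling
#' weights grouped into strata/PSUs; and a population-average quarterly
#' death hazard calibrated so the expected cumulative second-year death
#' fraction is 0.62%.
#'
#' @param n_subjects number of subjects.
#' @param n_continuous,n_nominal,n_ordinal counts of base variables by kind.
#' @param nominal_levels integer vector of per-variable level counts
#'   (length `n_nominal`, each >= 2).
#' @param redundancy_pairs number of extra variables generated as strictly
#'   monotone transforms of earlier continuous variables (Spearman rho = 1).
#' @param reserved_code_rates named probabilities for injecting reserved
#'   codes; allowed names "-1", "-3", "-7", "-8", "-9". Code -2
#'   ("same as previous round") is never generated because the cohort is
#'   single-wave.
#' @param reserved_code_frac fraction of variables eligible for reserved-code
#'   injection.
#' @param latent_effect log-odds increase in quarterly death hazard per unit
#'   of the latent risk factor.
#' @param baseline_quarterly_death_prob population-average quarterly death
#'   probability; default solves 1 - (1-p)^4 = 0.0062 so the expected
#'   cumulative second-year death fraction is 0.62%.
#' @param n_strata,psus_per_stratum sampling design layout.
#' @param weight_dispersion log-scale SD of the lognormal weights (0 gives
#'   equal weights).
#' @param nominal_population weights are normalized to sum to this total.
#' @param seed integer seed making generation fully reproducible.
#' @return an object of class `cohort_config` (a validated list).
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 500, n_continuous = 5,
#'                      n_nominal = 2, n_ordinal = 1,
#'                      nominal_levels = c(3, 4), seed = 1)
cohort_config <- function(n_subjects = 20000L,
                          n_continuous = 15L,
                          n_nominal = 68L,
                          n_ordinal = 3L,
                          nominal_levels = NULL,
                          redundancy_pairs = 10L,
                          reserved_code_rates = c("-1" = 0.002, "-3" = 0.0005,
                                                  "-7" = 0.001, "-8" = 0.001,
                                                  "-9" = 0.0005),
                          reserved_code_frac = 0.3,
                          latent_effect = 1,
                          baseline_quarterly_death_prob = NULL,
                          n_strata = 100L,
                          psus_per_stratum = 2L,
                          weight_dispersion = 0.5,
                          nominal_population = 2.8e8,
                          seed = 1L) {
  if (is.null(baseline_quarterly_death_prob)) {
    # quarterly hazard whose 4-quarter cumulative risk is 0.62%
    baseline_quarterly_death_prob <- 1 - (1 - 0.0062)^(1 / 4)
  }
  if (is.null(nominal_levels)) {
    # level counts chosen so sum(k - 1) = 184 at the default 68 nominals
    nominal_levels <- rep(c(2L, 3L, 5L), c(12L, 26L, 30L))
    nominal_levels <- rep_len(nominal_levels, n_nominal)
  }
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_continuous = as.integer(n_continuous),
              n_nominal = as.integer(n_nominal),
              n_ordinal = as.integer(n_ordinal),
              nominal_levels = as.integer(nominal_levels),
              redundancy_pairs = as.integer(redundancy_pairs),
              reserved_code_rates = reserved_code_rates,
              reserved_code_frac = reserved_code_frac,
              latent_effect = latent_effect,
              baseline_quarterly_death_prob = baseline_quarterly_death_prob,
              n_strata = as.integer(n_strata),
              psus_per_stratum = as.integer(psus_per_stratum),
              weight_dispersion = weight_dispersion,
              nominal_population = nominal_population,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot_config(cfg$n_subjects >= 1L, "n_subjects must be positive")
  stopifnot_config(cfg$n_continuous >= 0L && cfg$n_nominal >= 0L &&
                     cfg$n_ordinal >= 0L, "variable counts must be nonnegative")
  stopifnot_config(cfg$n_continuous + cfg$n_nominal + cfg$n_ordinal >= 1L,
                   "at least one variable is required")
  stopifnot_config(length(cfg$nominal_levels) == cfg$n_nominal,
                   "nominal_levels must have length n_nominal")
  stopifnot_config(all(cfg$nominal_levels >= 2L),
                   "nominal level counts must be >= 2")
  stopifnot_config(cfg$redundancy_pairs >= 0L &&
                     cfg$redundancy_pairs <= cfg$n_continuous,
                   "redundancy_pairs must be between 0 and n_continuous")
  r <- cfg$reserved_code_rates
  stopifnot_config(all(r >= 0 & r <= 1), "reserved code rates must be in [0,1]")
  stopifnot_config(all(names(r) %in% c("-1", "-3", "-7", "-8", "-9")),
                   "reserved code names must be among -1,-3,-7,-8,-9")
  stopifnot_config(cfg$reserved_code_frac >= 0 && cfg$reserved_code_frac <= 1,
                   "reserved_code_frac must be in [0,1]")
  p <- cfg$baseline_quarterly_death_prob
  stopifnot_config(is.numeric(p) && p > 0 && p < 1,
                   "baseline_quarterly_death_prob must be in (0,1)")
  stopifnot_config(cfg$n_strata >= 1L && cfg$psus_per_stratum >= 1L,
                   "strata/PSU counts must be positive")
  stopifnot_config(cfg$weight_dispersion >= 0,
                   "weight_dispersion must be >= 0")
  invisible(cfg)
}

stopifnot_config <- function(ok, msg) {
  if (!isTRUE(ok)) stop("invalid cohort configuration: ", msg, call. = FALSE)
}

# Intercept b0 such that the population-average quarterly hazard
# E[plogis(b0 + beta * F)], F ~ N(0,1), equals the target p. Keeps the
# marginal mortality rate calibrated whatever the latent effect size.
solve_hazard_intercept <- function(p, beta) {
  if (beta == 0) return(stats::qlogis(p))
  marginal <- function(b0) {
    stats::integrate(function(f) stats::plogis(b0 + beta * f) * stats::dnorm(f),
                     -8, 8, rel.tol = 1e-10)$value - p
  }
  stats::uniroot(marginal, lower = stats::qlogis(p) - 10 * abs(beta),
                 upper = stats::qlogis(p) + 1, tol = 1e-12)$root
}

#' Generate a synthetic survey cohort
#'
#' Draws a cohort from a one-factor latent risk model. Continuous
#' variables load on a standard-normal latent factor with loadings spread
#' over \[0.2, 0.8\]; ordinal variables are coarsened cuts of a noisy copy
#' of the factor; nominal variables are independent multinomials.
#' `redundancy_pairs` additional variables are strictly monotone
#' (exponential) transforms of the first continuous variables, giving
#' designed Spearman-rank redundancy. Reserved codes are injected
#' afterwards into an eligible subset of variables at the configured
#' rates. Quarterly death in the second year follows a Bernoulli hazard
#' `plogis(b0 + latent_effect * factor)` with `b0` calibrated so the
#' population-average hazard equals `baseline_quarterly_death_prob`.
#'
#' @param config a [cohort_config()].
#' @return an object of class `survey_cohort`: a list with
#'   \describe{
#'     \item{values}{numeric matrix subjects x variables (categoricals as
#'       integer level codes; reserved codes as negative sentinels)}
#'     \item{meta}{data frame of variable name, kind, number of levels,
#'       redundancy partner}
#'     \item{subjects}{data frame with id, weight, stratum, psu, age, sex,
#'       race, death_quarter (NA = survived), death_month (1..12, NA)}
#'     \item{config}{the generating configuration}
#'     \item{truth}{latent factor, loadings and per-subject hazard, kept
#'       for parameter-recovery checks}
#'   }
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 200, n_continuous = 5,
#'                                      n_nominal = 0, n_ordinal = 0,
#'                                      redundancy_pairs = 2, seed = 42))
#' table(coh$subjects$death_quarter, useNA = "ifany")
generate_cohort <- function(config) {
  validate_cohort_config(config)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_subjects

  f <- stats::rnorm(n)

  cols <- list()
  meta <- list()

  if (cfg$n_continuous > 0L) {
    lam <- seq(0.8, 0.2, length.out = max(cfg$n_continuous, 2L))[seq_len(cfg$n_continuous)]
    for (j in seq_len(cfg$n_continuous)) {
      x <- lam[j] * f + sqrt(1 - lam[j]^2) * stats::rnorm(n)
      nm <- sprintf("cont%02d", j)
      cols[[nm]] <- x
      meta[[nm]] <- list(kind = "continuous", n_levels = NA_integer_,
                         partner = NA_character_)
    }
  } else {
    lam <- numeric(0)
  }

  if (cfg$redundancy_pairs > 0L) {
    for (j in seq_len(cfg$redundancy_pairs)) {
      src <- sprintf("cont%02d", j)
      nm <- sprintf("dup%02d", j)
      # strictly increasing transform: identical ranks, Spearman rho = 1
      cols[[nm]] <- exp(cols[[src]] / 2)
      meta[[nm]] <- list(kind = "continuous", n_levels = NA_integer_,
                         partner = src)
    }
  }

  if (cfg$n_ordinal > 0L) {
    for (j in seq_len(cfg$n_ordinal)) {
      g <- 0.5 * f + sqrt(0.75) * stats::rnorm(n)
      br <- stats::quantile(g, c(0, 0.4, 0.7, 0.9, 1))
      x <- as.integer(cut(g, breaks = unique(br), include.lowest = TRUE))
      nm <- sprintf("ord%02d", j)
      cols[[nm]] <- x
      meta[[nm]] <- list(kind = "ordinal", n_levels = max(x),
                         partner = NA_character_)
    }
  }

  if (cfg$n_nominal > 0L) {
    for (j in seq_len(cfg$n_nominal)) {
      k <- cfg$nominal_levels[j]
      pr <- stats::rgamma(k, shape = 2) + 0.2
      x <- sample.int(k, n, replace = TRUE, prob = pr / sum(pr))
      nm <- sprintf("nom%02d", j)
      cols[[nm]] <- x
      meta[[nm]] <- list(kind = "nominal", n_levels = k,
                         partner = NA_character_)
    }
  }

  values <- do.call(cbind, cols)
  colnames(values) <- names(cols)
  meta <- data.frame(name = names(meta),
                     kind = vapply(meta, `[[`, "", "kind"),
                     n_levels = vapply(meta, `[[`, 1L, "n_levels"),
                     partner = vapply(meta, `[[`, "", "partner"),
                     stringsAsFactors = FALSE, row.names = NULL)

  # reserved-code injection into an eligible subset of variables
  rates <- cfg$reserved_code_rates
  if (length(rates) > 0 && any(rates > 0) && cfg$reserved_code_frac > 0) {
    p_vars <- ncol(values)
    n_elig <- max(1L, round(cfg$reserved_code_frac * p_vars))
    eligible <- sort(sample.int(p_vars, n_elig))
    for (j in eligible) {
      for (code_name in names(rates)) {
        rate <- rates[[code_name]]
        if (rate <= 0) next
        hit <- stats::runif(n) < rate
        values[hit, j] <- as.numeric(code_name)
      }
    }
  }

  # survey design
  w <- stats::rlnorm(n, 0, cfg$weight_dispersion)
  w <- w / sum(w) * cfg$nominal_population
  stratum <- sample.int(cfg$n_strata, n, replace = TRUE)
  psu_in_stratum <- sample.int(cfg$psus_per_stratum, n, replace = TRUE)
  psu <- (stratum - 1L) * cfg$psus_per_stratum + psu_in_stratum

  # demographics (not tied to the latent factor; the adjusted screening
  # model must still run, not find signal here)
  age <- pmin(90, pmax(0, round(stats::rnorm(n, 38, 22))))
  sex <- factor(ifelse(stats::runif(n) < 0.515, "female", "male"),
                levels = c("male", "female"))
  race_levels <- c("white", "black", "amindian_alnative", "asian",
                   "hawaiian_pacific", "multiple")
  race <- factor(sample(race_levels, n, replace = TRUE,
                        prob = c(0.81, 0.13, 0.01, 0.038, 0.004, 0.008)),
                 levels = race_levels)

  # quarterly mortality
  b0 <- solve_hazard_intercept(cfg$baseline_quarterly_death_prob,
                               cfg$latent_effect)
  hazard <- stats::plogis(b0 + cfg$latent_effect * f)
  u <- matrix(stats::runif(4L * n), nrow = n)
  death_quarter <- rep(NA_integer_, n)
  for (q in 4:1) death_quarter[u[, q] < hazard] <- q
  death_month <- ifelse(is.na(death_quarter), NA_integer_,
                        (death_quarter - 1L) * 3L +
                          sample.int(3L, n, replace = TRUE))

  subjects <- data.frame(id = seq_len(n), weight = w, stratum = stratum,
                         psu = psu, age = age, sex = sex, race = race,
                         death_quarter = death_quarter,
                         death_month = as.integer(death_month))

  structure(list(values = values, meta = meta, subjects = subjects,
                 config = cfg,
                 truth = list(factor = f, loadings = lam,
                              hazard = hazard, intercept = b0)),
            class = "survey_cohort")
}

#' Generate a null cohort (no variable-outcome association)
#'
#' Same generator with the latent effect forced to zero: the outcome is
#' independent of every variable, so any screening rejection is a false
#' positive. Used for type-I-error calibration.
#'
#' @inheritParams generate_cohort
#' @return a `survey_cohort`.
#' @export
make_two_arm_null <- function(config) {
  config$latent_effect <- 0
  generate_cohort(config)
}

#' @export
print.survey_cohort <- function(x, ...) {
  n_dead <- sum(!is.na(x$subjects$death_quarter))
  cat(sprintf("survey_cohort: %d subjects x %d variables (%d continuous, %d ordinal, %d nominal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$meta$kind == "continuous"), sum(x$meta$kind == "ordinal"),
              sum(x$meta$kind == "nominal")))
  cat(sprintf("  deaths in year 2: %d (%.2f%% unweighted)\n",
              n_dead, 100 * n_dead / nrow(x$values)))
  cat(sprintf("  design: %d strata x %d PSUs, weights sum %.3g\n",
              x$config$n_strata, x$config$psus_per_stratum,
              sum(x$subjects$weight)))
  invisible(x)
}

#' Write / read a survey cohort as CSV plus a JSON codebook
#'
#' `write_cohort()` writes `values.csv` (variable matrix), `subjects.csv`
#' (design, demographics, outcome) and `codebook.json` (variable kinds,
#' level counts, reserved-code semantics, generator config) into `dir`.
#' `read_cohort()` reloads them into a `survey_cohort` (without the
#' generator truth, which is not serialized).
#'
#' @param cohort a `survey_cohort`.
#' @param dir output directory, created if needed.
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` a
#'   `survey_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(cohort$values),
                   file.path(dir, "values.csv"), row.names = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  codebook <- list(
    variables = cohort$meta,
    reserved_codes = list(`-1` = "inapplicable",
                          `-2` = "same as previous round",
                          `-3` = "no data in round", `-7` = "refused",
                          `-8` = "do not know", `-9` = "not ascertained"),
    config = unclass(cohort$config))
  jsonlite::write_json(codebook, file.path(dir, "codebook.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  values <- as.matrix(utils::read.csv(file.path(dir, "values.csv")))
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                              stringsAsFactors = FALSE)
  subjects$sex <- factor(subjects$sex, levels = c("male", "female"))
  race_levels <- c("white", "black", "amindian_alnative", "asian",
                   "hawaiian_pacific", "multiple")
  subjects$race <- factor(subjects$race, levels = race_levels)
  codebook <- jsonlite::read_json(file.path(dir, "codebook.json"),
                                  simplifyVector = TRUE)
  meta <- as.data.frame(codebook$variables, stringsAsFactors = FALSE)
  cfg <- codebook$config
  cfg$reserved_code_rates <- unlist(cfg$reserved_code_rates)
  class(cfg) <- "cohort_config"
  structure(list(values = values, meta = meta, subjects = subjects,
                 config = cfg, truth = NULL),
            class = "survey_cohort")
}
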