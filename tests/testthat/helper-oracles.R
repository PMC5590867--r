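# Independent oracles used to cross-check the package's numerics.

# Newton-Raphson (IRLS) logistic regression, written from the likelihood
# equations; independent of stats::glm.
irls_logistic_oracle <- function(X, y, w = rep(1, length(y)),
                                 tol = 1e-12, max_iter = 100L) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- w * mu * (1 - mu)
    score <- crossprod(X, w * (y - mu))
    info <- crossprod(X, W * X)
    step <- solve(info, score)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  names(beta) <- colnames(X)
  beta
}

# Power iteration with deflation: leading eigenpairs of a symmetric PSD
# matrix, one at a time.
power_eigen_oracle <- function(C, tol = 1e-12, max_iter = 10000L) {
  p <- ncol(C)
  vals <- numeric(p)
  vecs <- matrix(0, p, p)
  A <- C
  for (k in seq_len(p)) {
    v <- rep(1 / sqrt(p), p)
    lam <- 0
    for (it in seq_len(max_iter)) {
      v_new <- A %*% v
      lam_new <- sqrt(sum(v_new^2))
      if (lam_new < 1e-14) { lam <- 0; break }
      v_new <- v_new / lam_new
      if (max(abs(abs(v_new) - abs(v))) < tol) {
        v <- v_new; lam <- lam_new; break
      }
      v <- v_new; lam <- lam_new
    }
    vals[k] <- lam
    vecs[, k] <- v
    A <- A - lam * tcrossprod(v)
  }
  list(values = vals, vectors = vecs)
}

# Textbook (unweighted) Kaplan-Meier product-limit estimator.
km_oracle <- function(time, event) {
  times <- sort(unique(time[event == 1]))
  surv <- numeric(length(times))
  s <- 1
  for (i in seq_along(times)) {
    t <- times[i]
    at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = times, surv = surv)
}

# A hand-built weighted_pca with given loadings, for unit tests of the
# index operations (which only consume loadings / n_variables).
fake_pca <- function(loadings) {
  loadings <- as.matrix(loadings)
  p <- nrow(loadings)
  structure(list(loadings = loadings,
                 eigenvalues = rep(1, ncol(loadings)),
                 means = NULL, scales = NULL,
                 n_variables = p,
                 var_names = paste0("V", seq_len(p))),
            class = "weighted_pca")
}

# Small cohort configurations reused across tests.
tiny_config <- function(...) {
  defaults <- list(n_subjects = 1500L, n_continuous = 6L, n_nominal = 2L,
                   n_ordinal = 1L, nominal_levels = c(3L, 4L),
                   redundancy_pairs = 2L, seed = 101L)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

# Continuous-only configuration: no reserved codes, redundancy or
# categoricals, so preprocessing reduces to standardization. Used by the
# simulation-heavy screening tests.
plain_config <- function(n_subjects, n_vars, latent_effect, seed) {
  cohort_config(n_subjects = n_subjects, n_continuous = n_vars,
                n_nominal = 0L, n_ordinal = 0L,
                nominal_levels = integer(0), redundancy_pairs = 0L,
                reserved_code_rates = numeric(0),
                latent_effect = latent_effect, seed = seed)
}

# Generate, standardize, fit the PCA and screen the full first-component
# score against mortality (unadjusted); returns the screen_result.
screen_pc1_once <- function(n_subjects, n_vars, latent_effect, seed) {
  coh <- generate_cohort(plain_config(n_subjects, n_vars, latent_effect,
                                      seed))
  std <- center_scale_weighted(coh$values, coh$subjects$weight)
  pca <- fit_weighted_pca(std$x, coh$subjects$weight)
  idx <- build_index(pca, std$x, pc = 1L, n = pca$n_variables)
  fit_discrete_time(expand_person_periods(coh), idx)
}
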