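make_cohort_values <- function(values, kinds, n_levels = NA_integer_) {
  # minimal survey_cohort shim for preprocessing unit tests
  p <- ncol(values)
  structure(list(
    values = values,
    meta = data.frame(name = colnames(values), kind = kinds,
                      n_levels = rep_len(n_levels, p),
                      partner = NA_character_),
    subjects = data.frame(id = seq_len(nrow(values)),
                          weight = rep(1, nrow(values)))),
    class = "survey_cohort")
}

test_that("reserved codes recode per sentinel semantics", {
  v <- cbind(contA = c(5, -8, 7, -1, 2),
             nomB = c(1, -1, 2, -7, 1),
             ordC = c(2, 3, -9, 1, -3),
             clean = c(1, 2, 3, 4, 5))
  coh <- make_cohort_values(v, c("continuous", "nominal", "ordinal",
                                 "continuous"),
                            n_levels = c(NA, 2L, 3L, NA))
  out <- recode_reserved(coh)
  # -8 ("do not know") and continuous -1 become missing
  expect_equal(out$values[, "contA"], c(5, NA, 7, NA, 2))
  # nominal -1 becomes an explicit extra level; -7 missing
  expect_equal(out$values[, "nomB"], c(1, 3, 2, NA, 1))
  expect_equal(out$meta$n_levels[2], 3L)
  # ordinal -9/-3 missing
  expect_equal(out$values[, "ordC"], c(2, 3, NA, 1, NA))
  # untouched column passes through
  expect_equal(out$values[, "clean"], v[, "clean"])
})

test_that("-2 carries the prior-round value forward when paired, else missing", {
  v <- cbind(x_r2 = c(-2, 5, -2), x_r1 = c(9, 1, 4), y = c(-2, 1, 2))
  coh <- make_cohort_values(v, rep("continuous", 3))
  coh$meta$prior_var <- c("x_r1", NA, NA)
  out <- recode_reserved(coh)
  expect_equal(out$values[, "x_r2"], c(9, 5, 4))
  expect_equal(out$values[, "y"], c(NA, 1, 2))
})

test_that("unknown negative sentinels in categoricals warn and pass through", {
  v <- cbind(nom = c(1, -4, 2))
  coh <- make_cohort_values(v, "nominal", 2L)
  expect_warning(out <- recode_reserved(coh), "not in the reserved-code set")
  expect_equal(out$values[, "nom"], c(1, -4, 2))
})

test_that("log transform fires exactly when it reduces absolute skewness", {
  set.seed(42)
  sym <- rnorm(500)
  expect_false(choose_log_transform(sym)$transformed)

  ln <- rlnorm(500)
  res <- choose_log_transform(ln)
  expect_true(res$transformed)
  # oracle: both skewnesses via an independent implementation
  expect_equal(res$skew_before, e1071::skewness(ln, type = 1),
               tolerance = 1e-12)
  expect_equal(res$skew_after, e1071::skewness(log(ln), type = 1),
               tolerance = 1e-12)

  with_zeros <- c(0, rlnorm(300))
  rz <- choose_log_transform(with_zeros)
  expect_true(all(is.finite(rz$values)))
  expect_equal(rz$shift, 1)

  const <- rep(3, 10)
  rc <- choose_log_transform(const)
  expect_false(rc$transformed)
  expect_match(rc$note, "constant")
  expect_error(choose_log_transform(c(1, 2)), "at least 3")
})

test_that("redundancy filter drops later near-rank-identical columns", {
  set.seed(7)
  x <- matrix(rnorm(200 * 4), 200, 4)
  colnames(x) <- paste0("v", 1:4)
  dup <- cbind(x, v1copy = x[, 1], v2mono = exp(x[, 2]))
  res <- spearman_redundancy_filter(dup, threshold = 0.9)
  expect_equal(res$retained, 1:4)  # duplicate and monotone copy dropped
  expect_setequal(res$dropped$column, c(5, 6))
  expect_equal(res$dropped$partner[res$dropped$column == 5], 1)

  # independent noise: everything retained (brute-force check all pairs)
  rho <- suppressWarnings(cor(x, method = "spearman"))
  expect_true(max(abs(rho[upper.tri(rho)])) <= 0.9)
  expect_equal(spearman_redundancy_filter(x)$retained, 1:4)
})

test_that("redundancy filter is idempotent and handles sparse pairs", {
  set.seed(8)
  x <- matrix(rnorm(100 * 5), 100, 5)
  x[, 5] <- x[, 4]^3  # monotone
  first <- spearman_redundancy_filter(x)
  second <- spearman_redundancy_filter(x[, first$retained, drop = FALSE])
  expect_equal(second$retained, seq_along(first$retained))

  sparse <- cbind(a = c(1, NA, NA, NA, 2), b = c(NA, 1, 2, 3, NA),
                  c = c(5, 2, 9, 1, 7))
  expect_warning(res <- spearman_redundancy_filter(sparse),
                 "fewer than 3 complete")
  expect_equal(res$retained, 1:3)
})

test_that("chained imputation beats unconditional mean fill on MCAR data", {
  set.seed(11)
  n <- 400
  f <- rnorm(n)
  full <- cbind(a = f + rnorm(n, sd = 0.3), b = -f + rnorm(n, sd = 0.3),
                c = 2 * f + rnorm(n, sd = 0.3))
  masked <- full
  holes <- matrix(runif(length(full)) < 0.05, n)
  masked[holes] <- NA

  imp <- impute_chained(masked, rep("continuous", 3), seed = 9L)
  expect_false(anyNA(imp))
  rmse_imp <- sqrt(mean((imp[holes] - full[holes])^2))
  mean_fill <- masked
  for (j in 1:3) mean_fill[holes[, j], j] <- mean(masked[, j], na.rm = TRUE)
  rmse_mean <- sqrt(mean((mean_fill[holes] - full[holes])^2))
  expect_lt(rmse_imp, rmse_mean)

  # determinism and identity on complete data
  expect_identical(imp, impute_chained(masked, rep("continuous", 3),
                                       seed = 9L))
  expect_identical(impute_chained(full, rep("continuous", 3)), full)
})

test_that("chained imputation restores valid levels for categoricals", {
  set.seed(12)
  n <- 300
  f <- rnorm(n)
  cat_full <- ifelse(f > 0.5, 3, ifelse(f > -0.5, 2, 1))
  x <- cbind(cont = f + rnorm(n, sd = 0.2), nom = cat_full)
  x[sample(n, 20), "nom"] <- NA
  imp <- impute_chained(x, c("continuous", "nominal"), seed = 2L)
  expect_true(all(imp[, "nom"] %in% 1:3))
  # conditional imputation should track the driving covariate
  miss <- is.na(x[, "nom"])
  expect_gt(mean(imp[miss, "nom"] == cat_full[miss]), 0.5)

  allmiss <- cbind(ok = 1:5, gone = rep(NA_real_, 5))
  expect_error(impute_chained(allmiss, c("continuous", "continuous")),
               "gone")
})

test_that("nominal expansion follows the k-1 reference-coding rule", {
  v <- cbind(nom3 = c(1, 2, 3, 1, 2, 3), ord = c(1, 2, 3, 4, 1, 2),
             cont = rnorm(6))
  res <- expand_nominal(v, c("nominal", "ordinal", "continuous"))
  expect_equal(ncol(res$expanded), 2 + 1 + 1)  # 3 levels -> 2 indicators
  expect_setequal(colnames(res$expanded)[1:2], c("nom3.2", "nom3.3"))
  expect_equal(res$expanded[, "ord"], v[, "ord"])  # ordinal passes through
  expect_equal(res$expanded[, "nom3.2"], as.numeric(v[, "nom3"] == 2))

  single <- cbind(nom1 = rep(1, 4), cont = rnorm(4))
  expect_warning(r1 <- expand_nominal(single, c("nominal", "continuous")),
                 "single observed level")
  expect_equal(ncol(r1$expanded), 1L)
})

test_that("expansion conserves the column-count law", {
  # pipeline conservation: expanded columns =
  # (#continuous + #ordinal) + sum over nominals of (levels - 1)
  set.seed(13)
  n <- 80
  levels_per <- c(2, 3, 5, 4)
  vals <- cbind(
    matrix(rnorm(n * 3), n, 3,
           dimnames = list(NULL, paste0("c", 1:3))),
    sapply(levels_per, function(k) rep_len(seq_len(k), n)))
  colnames(vals)[4:7] <- paste0("n", 1:4)
  kinds <- c(rep("continuous", 3), rep("nominal", 4))
  res <- expand_nominal(vals, kinds)
  expect_equal(ncol(res$expanded), 3 + sum(levels_per - 1))
  expect_equal(nrow(res$map), ncol(res$expanded))
})

test_that("weighted standardization hits exact weighted moments", {
  set.seed(14)
  x <- matrix(rnorm(300 * 4, mean = 5, sd = 3), 300, 4)
  colnames(x) <- paste0("v", 1:4)
  w <- rlnorm(300)
  res <- center_scale_weighted(x, w)
  wn <- w / sum(w)
  for (j in 1:4) {
    expect_lt(abs(sum(wn * res$x[, j])), 1e-10)
    expect_lt(abs(sum(wn * res$x[, j]^2) - 1), 1e-10)
  }
  # equal weights reduce to classical z-scoring (population sd)
  eq <- center_scale_weighted(x, rep(2, 300))
  z <- scale(x) * sqrt(300 / 299)
  expect_equal(unname(eq$x), unname(z[, ]), tolerance = 1e-12)

  withconst <- cbind(x, k = rep(7, 300))
  expect_warning(rc <- center_scale_weighted(withconst, w), "zero-variance")
  expect_equal(rc$dropped, "k")
  expect_equal(ncol(rc$x), 4L)
  expect_error(center_scale_weighted(x, rep(0, 300)), "zero")
})

test_that("full preprocessing pipeline produces a standardized PCA matrix", {
  coh <- generate_cohort(tiny_config())
  prep <- preprocess_cohort(coh, seed = 3L)
  expect_false(anyNA(prep$x))
  wn <- prep$weights / sum(prep$weights)
  expect_lt(max(abs(colSums(wn * prep$x))), 1e-10)
  expect_lt(max(abs(colSums(wn * prep$x^2) - 1)), 1e-10)
  # redundant duplicates must have been filtered out
  dup_names <- coh$meta$name[!is.na(coh$meta$partner) &
                               coh$meta$partner != ""]
  expect_false(any(dup_names %in% prep$retained))
  # conservation law on the retained set
  kinds <- prep$kinds
  n_pass <- sum(kinds != "nominal")
  expect_equal(ncol(prep$x) + length(prep$dropped_constant),
               n_pass + sum(vapply(
                 which(kinds == "nominal"),
                 function(j) length(unique(prep$map$level[
                   prep$map$source == prep$retained[j] &
                     !is.na(prep$map$level)])),
                 1L)))
})
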