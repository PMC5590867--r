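#' Mine all PCA-loading-weighted indices of a cohort against mortality
#'
#' The full pipeline in one call: preprocessing (reserved-code recoding,
#' skewness-gated log transforms, Spearman redundancy filtering, chained
#' imputation, dummy expansion, weighted standardization), survey-weighted
#' PCA, enumeration of every cumulative loading-ordered index, and a
#' discrete-time event-history screen of each index (unadjusted and
#' adjusted for age, sex, race), summarized by index size.
#'
#' @param cohort a `survey_cohort` from [generate_cohort()] /
#'   [read_cohort()].
#' @param rho Spearman redundancy threshold (default 0.9).
#' @param alpha significance level for the screen (default 0.05; no
#'   multiplicity correction — the expected false-discovery volume at this
#'   level is part of what the method illustrates).
#' @param n_iterations imputation sweeps.
#' @param seed seed for the imputation stage.
#' @param verbose progress messages during the screen.
#' @return object of class `index_screen`: list with `preprocess`
#'   (a `preprocess_result`), `pca` (`weighted_pca`), `screen`
#'   (`screen_table`), `summary` (`size_bin_summary`), `impact`
#'   (`publication_impact` for indices significant in both models),
#'   `alpha`, `call`.
#' @export
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(n_subjects = 2000, n_continuous = 5,
#'                                      n_nominal = 0, n_ordinal = 0,
#'                                      redundancy_pairs = 0, seed = 7))
#' fit <- index_screen(coh)
#' summary(fit)
#' }
index_screen <- function(cohort, rho = 0.9, alpha = 0.05,
                         n_iterations = 5L, seed = 1L, verbose = FALSE) {
  prep <- preprocess_cohort(cohort, rho = rho, n_iterations = n_iterations,
                            seed = seed)
  pca <- fit_weighted_pca(prep$x, prep$weights,
                          means = prep$means, scales = prep$scales)
  st <- screen_all(cohort, pca, prep$x, alpha = alpha, adjusted = "both",
                   verbose = verbose)
  sm <- summarize_by_size(st)
  n_both <- sm$n_significant[sm$bin == "All" & sm$family == "both"]
  structure(list(preprocess = prep, pca = pca, screen = st, summary = sm,
                 impact = publication_impact(n_both), alpha = alpha,
                 call = match.call()),
            class = "index_screen")
}

#' @export
print.index_screen <- function(x, ...) {
  N <- x$pca$n_variables
  all_rows <- x$summary[x$summary$bin == "All", ]
  cat(sprintf("index_screen: %d variables -> %d cumulative weighted indices\n",
              N, N^2))
  for (i in seq_len(nrow(all_rows))) {
    r <- all_rows[i, ]
    cat(sprintf("  significant (%s, p < %g): %d / %d (%.2f%%)\n",
                r$family, x$alpha, r$n_significant,
                r$n_significant + r$n_insignificant, r$pct_significant))
  }
  invisible(x)
}

#' @export
summary.index_screen <- function(object, ...) {
  cat("Significance of weighted indices by index size (alpha =",
      object$alpha, ")\n\n")
  print.data.frame(object$summary, row.names = FALSE)
  cat("\n")
  print(object$impact)
  invisible(object$summary)
}

#' @export
coef.index_screen <- function(object, ...) {
  object$screen
}

#' Plot index p-values by index size
#'
#' One point per index and model family: -log10 p against the number of
#' input variables, with the significance threshold drawn as a horizontal
#' line.
#'
#' @param x an `index_screen`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.index_screen <- function(x, ...) {
  st <- x$screen[x$screen$converged & !is.na(x$screen$p), ]
  col <- ifelse(st$model == "unadjusted", "#00000055", "#d6604d55")
  graphics::plot(st$n, -log10(pmax(st$p, 1e-300)), pch = 16, col = col,
                 xlab = "number of input variables in index",
                 ylab = expression(-log[10]~p),
                 main = "Index screening p-values", ...)
  graphics::abline(h = -log10(x$alpha), lty = 2)
  graphics::legend("topright", legend = c("unadjusted", "adjusted"),
                   col = c("#000000", "#d6604d"), pch = 16, bty = "n")
  invisible(x)
}
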