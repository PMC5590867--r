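#' Rank variables by absolute loading within a component
#'
#' The enumeration order of an index family: variables sorted by
#' descending absolute loading on the chosen component, ties broken by
#' ascending original column index.
#'
#' @param model a `weighted_pca`.
#' @param pc component number (1..N).
#' @return integer permutation of 1..N.
#' @export
rank_variables_by_loading <- function(model, pc) {
  N <- model$n_variables
  if (length(pc) != 1L || pc < 1L || pc > N) {
    stop(sprintf("pc must be in 1..%d", N))
  }
  l <- model$loadings[, pc]
  order(-abs(l), seq_along(l))
}

#' Enumerate all cumulative index specifications
#'
#' One index per (component, number of leading variables) pair: N indices
#' per component, N^2 in total, listed component-major with n ascending.
#'
#' @param model a `weighted_pca`, or a plain variable count N.
#' @return data frame with columns `pc` and `n` (N^2 rows).
#' @export
#' @examples
#' nrow(enumerate_index_specs(367)) # 134689
enumerate_index_specs <- function(model) {
  N <- if (inherits(model, "weighted_pca")) model$n_variables
       else as.integer(model)
  if (is.na(N) || N < 1L) stop("need a fitted model or a positive count")
  data.frame(pc = rep(seq_len(N), each = N),
             n = rep(seq_len(N), times = N))
}

#' Build one cumulative loading-weighted index
#'
#' The value for subject s is `sum_{i=1..n} L_ord[i] * x_{s, ord[i]}`
#' where `ord` ranks variables by descending |loading| on component `pc`.
#' With `n = N` the index equals the component score itself.
#'
#' @param model a `weighted_pca`.
#' @param x standardized matrix (the same scale the PCA was fitted on).
#' @param pc component number.
#' @param n number of leading variables included (1..N).
#' @return numeric vector of per-subject index values, with the spec
#'   (`pc`, `n`, `ordering`) attached as attribute `"spec"`.
#' @export
build_index <- function(model, x, pc, n) {
  N <- model$n_variables
  if (n < 1L || n > N) stop(sprintf("n must be in 1..%d", N))
  ord <- rank_variables_by_loading(model, pc)
  sel <- ord[seq_len(n)]
  v <- as.vector(x[, sel, drop = FALSE] %*% model$loadings[sel, pc])
  attr(v, "spec") <- list(pc = pc, n = n, ordering = ord)
  v
}

#' Long-format catalog of every cumulative index
#'
#' One row per (component, position): the variable entering the family
#' at that position, its loading weight, and the position itself (the
#' index `Index_pc.n` sums rows with position <= n).
#'
#' @param model a `weighted_pca`.
#' @return data frame with columns `pc`, `position`, `variable`,
#'   `loading` (N^2 rows).
#' @export
index_catalog <- function(model) {
  N <- model$n_variables
  out <- vector("list", N)
  for (pc in seq_len(N)) {
    ord <- rank_variables_by_loading(model, pc)
    out[[pc]] <- data.frame(pc = pc, position = seq_len(N),
                            variable = model$var_names[ord],
                            loading = model$loadings[ord, pc],
                            row.names = NULL)
  }
  do.call(rbind, out)
}

#' Transmit an index coefficient to its input variables
#'
#' An index fitted with coefficient `beta_index` implies per-variable
#' coefficients `beta_index * w_i` where `w_i` is the loading weight of
#' each included variable; variables outside the index get 0. The implied
#' linear predictor contribution `sum_i (beta_index * w_i) * x_i` equals
#' `beta_index` times the index value exactly.
#'
#' @param beta_index fitted coefficient of the index.
#' @param model a `weighted_pca`.
#' @param pc,n the index identity.
#' @return named numeric vector, one entry per model variable.
#' @export
implied_coefficients <- function(beta_index, model, pc, n) {
  ord <- rank_variables_by_loading(model, pc)
  out <- numeric(model$n_variables)
  names(out) <- model$var_names
  sel <- ord[seq_len(n)]
  out[sel] <- beta_index * model$loadings[sel, pc]
  out
}
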