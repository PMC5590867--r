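#' Summarize screening significance by index size
#'
#' Bins indices by the number of input variables (1, 2-30, 31-70, >= 71,
#' plus an "All" row) and counts significant / insignificant indices for
#' three model families: significant in both the unadjusted and adjusted
#' model, in the adjusted model, and in the unadjusted model. Percentages
#' are 100 * sig / (sig + insig) rounded half-up to 2 decimals; an empty
#' bin reports NA. Non-converged fits count as insignificant and are also
#' tallied separately.
#'
#' @param screen_table a `screen_table` from [screen_all()] containing
#'   both model families.
#' @return data frame of class `size_bin_summary`: one row per bin x
#'   family with columns `bin`, `family`, `n_insignificant`,
#'   `n_significant`, `pct_significant`, `n_nonconverged`.
#' @export
summarize_by_size <- function(screen_table) {
  st <- screen_table
  un <- st[st$model == "unadjusted", c("pc", "n", "significant", "converged")]
  ad <- st[st$model == "adjusted", c("pc", "n", "significant", "converged")]
  if (nrow(un) == 0L || nrow(ad) == 0L) {
    stop("screen table must contain both unadjusted and adjusted fits")
  }
  m <- merge(un, ad, by = c("pc", "n"), suffixes = c("_un", "_ad"))
  m$sig_both <- m$significant_un & m$significant_ad

  bin_of <- function(n) {
    cut(n, breaks = c(0, 1, 30, 70, Inf),
        labels = c("1 variable", "2 to 30 variables", "31 to 70 variables",
                   "71 variables or more"))
  }
  m$bin <- bin_of(m$n)

  fam <- list(both = m$sig_both, adjusted = m$significant_ad,
              unadjusted = m$significant_un)
  nonconv <- list(both = !(m$converged_un & m$converged_ad),
                  adjusted = !m$converged_ad, unadjusted = !m$converged_un)
  bins <- c(levels(m$bin), "All")
  rows <- list()
  for (family in names(fam)) {
    sig <- fam[[family]]
    for (b in bins) {
      in_bin <- if (b == "All") rep(TRUE, nrow(m)) else m$bin == b
      ns <- sum(sig[in_bin]); ni <- sum(!sig[in_bin])
      pct <- if (ns + ni == 0L) NA_real_ else
        round_half_up(100 * ns / (ns + ni), 2)
      rows[[length(rows) + 1L]] <- data.frame(
        bin = b, family = family, n_insignificant = ni, n_significant = ns,
        pct_significant = pct,
        n_nonconverged = sum(nonconv[[family]][in_bin]))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("size_bin_summary", "data.frame")
  out
}

#' Percentage of significant indices
#'
#' The summary-table identity: 100 * significant / (significant +
#' insignificant), rounded half-up to two decimals.
#'
#' @param n_significant,n_insignificant counts.
#' @return percentage on the 0-100 scale.
#' @export
#' @examples
#' pct_significant(208, 159)  # 56.68
pct_significant <- function(n_significant, n_insignificant) {
  round_half_up(100 * n_significant / (n_significant + n_insignificant), 2)
}

#' Publication-impact arithmetic for significant indices
#'
#' Converts a count of significant indices into the whimsical but exact
#' quotients of the proposed publication cycle: years of academic tenure
#' sustained by publishing `per_year` indices annually, and years of
#' journal publishing for a journal printing `per_journal` articles
#' annually. Exact quotients are returned; two-decimal and one-decimal
#' half-up renderings are also emitted.
#'
#' @param n_significant number of significant indices (>= 0).
#' @param per_year indices a researcher publishes per year (default 4).
#' @param per_journal articles a journal publishes per year (default 66).
#' @return object of class `publication_impact`: list with
#'   `n_significant`, `tenure_years`, `journal_years` (exact),
#'   `tenure_years_2dp`, `journal_years_2dp`, `journal_years_1dp`.
#' @export
#' @examples
#' publication_impact(5161)$tenure_years  # 1290.25
publication_impact <- function(n_significant, per_year = 4,
                               per_journal = 66) {
  if (n_significant < 0) stop("n_significant must be nonnegative")
  tenure <- n_significant / per_year
  journal <- n_significant / per_journal
  structure(list(n_significant = n_significant,
                 per_year = per_year, per_journal = per_journal,
                 tenure_years = tenure, journal_years = journal,
                 tenure_years_2dp = round_half_up(tenure, 2),
                 journal_years_2dp = round_half_up(journal, 2),
                 journal_years_1dp = round_half_up(journal, 1)),
            class = "publication_impact")
}

#' @export
print.publication_impact <- function(x, ...) {
  cat(sprintf("%d significant indices -> %.2f years of academic tenure (%d/year)\n",
              x$n_significant, x$tenure_years_2dp, x$per_year))
  cat(sprintf("  or %.2f years of journal publishing (%d articles/year)\n",
              x$journal_years_2dp, x$per_journal))
  invisible(x)
}

#' Export the screening report
#'
#' Writes the size-bin summary as CSV and a Markdown report with the
#' summary table, the publication-impact paragraph and run metadata.
#' Output is deterministic: identical inputs give byte-identical files.
#'
#' @param summary a `size_bin_summary`.
#' @param impact a `publication_impact`.
#' @param dir output directory (created if needed).
#' @param metadata named list recorded in the report (e.g. seed, alpha,
#'   config hash).
#' @param screen optional `screen_table`; when given it is written as
#'   `screen_table.csv` (one row per pc, n, model).
#' @return invisibly, the paths written.
#' @export
export_report <- function(summary, impact, dir, metadata = list(),
                          screen = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(dir, "significance_by_size.csv")
  md_path <- file.path(dir, "report.md")
  utils::write.csv(summary, csv_path, row.names = FALSE)
  screen_path <- NULL
  if (!is.null(screen)) {
    screen_path <- file.path(dir, "screen_table.csv")
    utils::write.csv(screen, screen_path, row.names = FALSE)
  }

  fam_label <- c(both = "Unadjusted and adjusted models",
                 adjusted = "Adjusted models",
                 unadjusted = "Unadjusted models")
  lines <- c("# Index mining report", "")
  if (length(metadata)) {
    lines <- c(lines, "## Run metadata", "",
               sprintf("- %s: %s", names(metadata),
                       vapply(metadata, function(v) paste(format(v), collapse = " "), "")),
               "")
  }
  lines <- c(lines, "## Significance of weighted indices by index size", "")
  for (family in unique(summary$family)) {
    s <- summary[summary$family == family, ]
    lines <- c(lines, sprintf("### %s", fam_label[[family]]), "",
               "| Index size | Insignificant (n) | Significant (n) | % significant |",
               "|---|---|---|---|",
               sprintf("| %s | %d | %d | %s |", s$bin, s$n_insignificant,
                       s$n_significant,
                       ifelse(is.na(s$pct_significant), "",
                              sprintf("%.2f%%", s$pct_significant))),
               "")
  }
  lines <- c(lines, "## Publication impact", "",
             sprintf(paste("The %d significant indices could sustain %.2f years of",
                           "academic tenure for a researcher publishing %d indices per",
                           "year, or %.2f years of publishing for a journal with an",
                           "annual volume of %d articles."),
                     impact$n_significant, impact$tenure_years_2dp,
                     impact$per_year, impact$journal_years_2dp,
                     impact$per_journal), "")
  writeLines(lines, md_path)
  paths <- c(csv = csv_path, markdown = md_path)
  if (!is.null(screen_path)) paths <- c(paths, screen = screen_path)
  invisible(paths)
}
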