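# Auxiliary contingency statistics and report rendering: Pearson chi-squared
# tests on edge-composition tables (Yates-corrected for 2x2), two-proportion
# comparisons, and fixed-layout renderings of fit results.

#' Pearson chi-squared test of a contingency table
#'
#' Wraps [stats::chisq.test()] with an explicit continuity-correction
#' policy: `"auto"` (default) applies the Yates correction exactly when the
#' table is 2x2, matching standard practice for edge-proportion
#' comparisons; `"on"` and `"off"` force it.
#'
#' @param counts A matrix or data frame of nonnegative counts (at least
#'   2x2, positive grand total).
#' @param correction `"auto"`, `"on"` or `"off"`.
#' @return A one-row tibble with `statistic`, `df`, `p.value` and
#'   `correction` (`"yates"` or `"none"`).
#' @examples
#' edges <- rbind(y2009 = c(187, 182, 646, 464),
#'                y2011 = c(168, 202, 549, 266))
#' pearson_chisq(edges)
#' @export
pearson_chisq <- function(counts, correction = c("auto", "on", "off")) {
  correction <- match.arg(correction)
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) stop("need at least a 2x2 table")
  if (any(counts < 0) || sum(counts) <= 0) {
    stop("counts must be nonnegative with positive total")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero row or column marginal")
  }
  is2x2 <- nrow(counts) == 2 && ncol(counts) == 2
  correct <- switch(correction, auto = is2x2, on = TRUE, off = FALSE)
  if (correct && !is2x2) {
    warning("Yates correction only defined for 2x2 tables; not applied")
    correct <- FALSE
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = unname(ht$p.value),
         correction = if (correct) "yates" else "none")
}

#' Compare two proportions via a 2x2 chi-squared test
#'
#' Reports both proportions at full precision and delegates the test to
#' [pearson_chisq()] on the implied 2x2 success/failure table with the
#' `"auto"` policy (Yates-corrected).
#'
#' @param successes_1,total_1 Count and denominator for condition 1.
#' @param successes_2,total_2 Count and denominator for condition 2.
#' @param correction Passed to [pearson_chisq()].
#' @return A one-row tibble with `prop_1`, `prop_2`, `statistic`, `df`,
#'   `p.value` and `correction`.
#' @examples
#' # alliance edges as a share of all edges, two observation periods
#' proportion_test(182, 1479, 202, 1185)
#' @export
proportion_test <- function(successes_1, total_1, successes_2, total_2,
                            correction = "auto") {
  stopifnot(total_1 > 0, total_2 > 0,
            successes_1 >= 0, successes_1 <= total_1,
            successes_2 >= 0, successes_2 <= total_2)
  tab <- rbind(c(successes_1, total_1 - successes_1),
               c(successes_2, total_2 - successes_2))
  res <- pearson_chisq(tab, correction = correction)
  dplyr::bind_cols(
    tibble(prop_1 = successes_1 / total_1, prop_2 = successes_2 / total_2),
    res
  )
}

#' Render a fit as an observed/expected class table
#'
#' One row per linkage class in canonical order; the observed column, then
#' one column per model step showing the expected count with the per-class
#' chi-squared cell in parentheses (counts and cells to 2 decimals). A
#' totals row carries each step's chi-squared total.
#'
#' @param fit A [maxent_fit()] object.
#' @return A tibble of formatted character columns (first column `class`,
#'   then `observed`, then one column per step).
#' @examples
#' render_class_table(maxent_fit(table1_fixture()$tally,
#'                               centering = "paper-table-1-compat"))
#' @export
render_class_table <- function(fit) {
  stopifnot(inherits(fit, "maxent_fit"))
  long <- fit_class_table(fit)
  wide <- long |>
    dplyr::mutate(cell = sprintf("%.2f (%.2f)", .data$expected, .data$chisq)) |>
    dplyr::select("step", "class", "cell") |>
    tidyr::pivot_wider(names_from = "step", values_from = "cell")
  out <- dplyr::bind_cols(
    tibble(class = wide$class,
           observed = as.character(fit$observed$observed)),
    wide[, -1]
  )
  totals <- vapply(fit$steps, function(s) sprintf("%.7g", s$total), "")
  dplyr::bind_rows(out, c(class = "total", observed = "",
                          setNames(totals, names(wide)[-1])))
}

#' Summarize chi-squared trajectories over several network pairs
#'
#' @param fits Named list of [maxent_fit()] objects (names label the
#'   network pairs).
#' @return A tibble with one row per pair: `pair`, then one column per
#'   step label holding that step's chi-squared total. Pairs fitted with
#'   different constraint sequences are aligned by step label.
#' @export
summarize_trajectory <- function(fits) {
  if (length(fits) == 0) return(tibble(pair = character()))
  stopifnot(all(vapply(fits, inherits, TRUE, "maxent_fit")))
  if (is.null(names(fits))) names(fits) <- paste0("pair_", seq_along(fits))
  purrr::imap_dfr(fits, function(fit, nm) {
    tot <- fit_totals(fit)
    dplyr::bind_cols(tibble(pair = nm), as_tibble(as.list(tot)))
  })
}

#' Write a class table or trajectory summary to CSV
#'
#' Deterministic writer (stable ordering, '.' decimal separator) for the
#' report tables.
#'
#' @param x A tibble from [render_class_table()] or
#'   [summarize_trajectory()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}
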