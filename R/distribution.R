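# Probability distributions over the 16 linkage states, and the exponential
# tilting machinery: tilt, moment functions, and the one-dimensional Lagrange
# multiplier solve by moment matching.

new_cell_distribution <- function(prob) {
  stopifnot(length(prob) == 16, all(is.finite(prob)), all(prob >= 0))
  if (abs(sum(prob) - 1) > 1e-12) stop("probabilities must sum to 1")
  st <- .state_space
  out <- as_tibble(cbind(st[c("state", "x1", "x2", "x3", "x4")], prob = prob))
  structure(out, class = c("cell_distribution", class(out)))
}

#' Turn a 16-value probability vector into a cell distribution
#'
#' @param prob Numeric vector of 16 nonnegative values summing to 1, either
#'   named by state or in the canonical state order of [linkage_states()].
#' @return A `cell_distribution` tibble (`state`, `x1`..`x4`, `prob`).
#' @export
cell_distribution <- function(prob) {
  if (!is.null(names(prob))) {
    prob <- prob[.state_space$state]
    if (anyNA(prob)) stop("`prob` must cover all 16 states")
  }
  new_cell_distribution(unname(prob))
}

#' @export
print.cell_distribution <- function(x, ...) {
  cat("<cell_distribution over 16 linkage states>\n")
  NextMethod()
}

dist_prob <- function(dist) {
  stopifnot(inherits(dist, "cell_distribution"))
  setNames(dist$prob, dist$state)
}

#' Independence (mean-field) null distribution
#'
#' The product distribution in which the four directed-edge indicators of a
#' cell are independent, each network's two directions sharing that network's
#' edge rate: `p(v) = pA^(x1+x2) (1-pA)^(2-x1-x2) pB^(x3+x4) (1-pB)^(2-x3-x4)`.
#' This is the mean-field null in which every pair of nodes is equally
#' likely to interact.
#'
#' @param p_a,p_b Per-direction edge rates of networks A and B, in `[0, 1]`.
#' @return A `cell_distribution`.
#' @examples
#' rates <- edge_rates(table1_fixture()$tally)$rate
#' independence_distribution(rates[1], rates[2])
#' @export
independence_distribution <- function(p_a, p_b) {
  stopifnot(p_a >= 0, p_a <= 1, p_b >= 0, p_b <= 1)
  st <- .state_space
  prob <- p_a^(st$x1 + st$x2) * (1 - p_a)^(2 - st$x1 - st$x2) *
    p_b^(st$x3 + st$x4) * (1 - p_b)^(2 - st$x3 - st$x4)
  new_cell_distribution(prob)
}

#' Model mean of a constraint function
#'
#' @param f A [constraint_function()].
#' @param dist A `cell_distribution`.
#' @return `sum(p(v) f(v))` over the 16 states.
#' @export
model_mean <- function(f, dist) {
  v <- constraint_values(f)
  sum(dist_prob(dist) * v[names(dist_prob(dist))])
}

#' Empirical mean of a constraint function under a tally
#'
#' @param f A [constraint_function()].
#' @param tally A [linkage_tally()].
#' @return `sum(count(v) f(v)) / N` over the full 16-state tally, where `N`
#'   is the tally's total cell count.
#' @export
empirical_mean <- function(f, tally) {
  stopifnot(inherits(tally, "linkage_tally"))
  v <- constraint_values(f)
  sum(tally$count * v[tally$state]) / tally_cells(tally)
}

#' Exponentially tilt a distribution by a constraint function
#'
#' Reweights `p'(v) = p(v) exp(lambda f(v)) / Z`; the result is the
#' maximum-entropy (minimum-KL) modification of `dist` among distributions
#' with the tilted mean of `f`. Computed in log space with max-subtraction
#' so large multipliers cannot overflow. Mirror symmetry of `dist` is
#' preserved whenever `f` is mirror-invariant.
#'
#' @param dist A `cell_distribution`.
#' @param f A [constraint_function()].
#' @param lambda Tilting parameter (Lagrange multiplier).
#' @return A `cell_distribution` with attribute `partition` holding the
#'   normalizing constant `Z = sum(p(v) exp(lambda f(v)))`.
#' @export
tilt_distribution <- function(dist, f, lambda) {
  p <- dist_prob(dist)
  v <- constraint_values(f)[names(p)]
  lf <- lambda * v
  shift <- max(lf)
  w <- p * exp(lf - shift)
  z <- sum(w)
  out <- new_cell_distribution(unname(w / z))
  attr(out, "partition") <- z * exp(shift)
  out
}

#' Solve the Lagrange multiplier by moment matching
#'
#' Finds the `lambda` for which the tilted model mean of `f` equals
#' `target`: the stationarity condition `d log Z / d lambda = target` of the
#' maximum-entropy problem. The tilted mean is strictly increasing in
#' `lambda` (its derivative is the tilted variance of `f`), so the root is
#' unique; it is located by bracket expansion from `[-1, 1]` followed by
#' safeguarded Newton steps with bisection fallback.
#'
#' @param dist The current (pre-tilt) `cell_distribution`.
#' @param f A [constraint_function()].
#' @param target The empirical mean the tilted model must match; must lie
#'   strictly between the minimum and maximum of `f` over states with
#'   positive probability.
#' @param tol Convergence tolerance on the matched moment.
#' @param max_iter Iteration cap.
#' @return The multiplier `lambda` (a single number).
#' @export
solve_lambda <- function(dist, f, target, tol = 1e-10, max_iter = 200L) {
  p <- dist_prob(dist)
  v <- constraint_values(f)[names(p)]
  support <- v[p > 0]
  if (diff(range(support)) == 0) {
    stop("constraint '", constraint_name(f),
         "' is degenerate (zero variance) under the current model")
  }
  if (target <= min(support) || target >= max(support)) {
    stop(sprintf(
      "target %.6g for '%s' outside the attainable open interval (%.6g, %.6g)",
      target, constraint_name(f), min(support), max(support)))
  }
  moment <- function(lam) {
    lf <- lam * v
    w <- p * exp(lf - max(lf))
    q <- w / sum(w)
    m <- sum(q * v)
    list(m = m, var = sum(q * (v - m)^2))
  }
  # expand a bracket around the root
  lo <- -1; hi <- 1
  for (k in seq_len(60)) {
    if (moment(lo)$m < target) break
    lo <- lo * 2
  }
  for (k in seq_len(60)) {
    if (moment(hi)$m > target) break
    hi <- hi * 2
  }
  if (moment(lo)$m >= target || moment(hi)$m <= target) {
    stop("failed to bracket the multiplier for '", constraint_name(f), "'")
  }
  lam <- (lo + hi) / 2
  for (it in seq_len(max_iter)) {
    mm <- moment(lam)
    if (abs(mm$m - target) < tol) return(lam)
    if (mm$m < target) lo <- lam else hi <- lam
    step <- (target - mm$m) / mm$var
    cand <- lam + step
    lam <- if (is.finite(cand) && cand > lo && cand < hi) cand
           else (lo + hi) / 2
  }
  mm <- moment(lam)
  if (abs(mm$m - target) < sqrt(tol)) return(lam)
  stop("multiplier solve for '", constraint_name(f),
       "' did not converge within ", max_iter, " iterations")
}

#' Expected class counts under a model
#'
#' The expected count of a class is `N * p(representative)`: the same
#' representative-orientation convention as the observed column of
#' [class_counts()], so observed and expected columns are directly
#' comparable.
#'
#' @param dist A `cell_distribution`.
#' @param n_cells Total census cell count `N` (e.g. [tally_cells()]).
#' @return A tibble with columns `class`, `symmetric` and `expected`.
#' @export
expected_class_counts <- function(dist, n_cells) {
  stopifnot(n_cells > 0)
  cl <- linkage_classes()
  p <- dist_prob(dist)
  tibble(class = cl$class, symmetric = cl$symmetric,
         expected = n_cells * unname(p[cl$class]))
}

#' Per-class chi-squared cells and total
#'
#' @param observed Tibble with `class` and `observed` (from [class_counts()]).
#' @param expected Tibble with `class` and `expected`
#'   (from [expected_class_counts()]).
#' @return A tibble with columns `class`, `observed`, `expected` and `chisq`
#'   (`(O - E)^2 / E`), carrying the total in attribute `total` (also
#'   available via [chisq_total()]). Classes with `observed = expected = 0`
#'   are excluded from the total with a warning; `expected = 0` with
#'   `observed > 0` is an error.
#' @export
chisq_table <- function(observed, expected) {
  stopifnot(setequal(observed$class, expected$class))
  out <- dplyr::inner_join(observed[c("class", "observed")],
                           expected[c("class", "expected")], by = "class")
  zero <- out$expected == 0
  if (any(zero & out$observed > 0)) {
    stop("expected count 0 with positive observed count in class ",
         out$class[zero & out$observed > 0][1])
  }
  if (any(zero)) {
    warning("class(es) with observed = expected = 0 excluded: ",
            paste(out$class[zero], collapse = ", "))
  }
  out$chisq <- ifelse(zero, NA_real_, (out$observed - out$expected)^2 / out$expected)
  structure(out, total = sum(out$chisq, na.rm = TRUE))
}

#' @rdname chisq_table
#' @param x A table returned by `chisq_table()`.
#' @export
chisq_total <- function(x) attr(x, "total")

#' Chi-squared critical value
#'
#' Upper quantile of the chi-squared distribution, used by the sequential
#' fit's stopping rule. At 9 degrees of freedom the 95% and 99% values are
#' 16.919 and 21.666.
#'
#' @param df Degrees of freedom (>= 1).
#' @param level Quantile level in (0, 1).
#' @return A single number.
#' @export
critical_value <- function(df, level) {
  stopifnot(df >= 1)
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)")
  qchisq(level, df = df)
}
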