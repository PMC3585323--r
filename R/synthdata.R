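# Synthetic paired networks: iid dyads drawn from a mirror-symmetric
# 16-state distribution in the tilted-exponential family, plus the packaged
# reference census and parameter-recovery experiments.

#' The packaged grooming/aggression reference census
#'
#' The observed linkage-class counts for the 2009 grooming (network A) and
#' aggression (network B) networks of a 77-animal captive rhesus macaque
#' group, under the `paper-n2` ordered-cell convention (16-state total
#' `77^2 = 5929`, implied directed edge totals 187 grooming and 645
#' aggression).
#'
#' @return A list with `tally` (a [linkage_tally()]) and `classes` (the
#'   10-class observed-count tibble).
#' @examples
#' table1_fixture()$classes
#' @export
table1_fixture <- function() {
  counts <- c("1000" = 100, "1100" = 28, "0010" = 435, "0011" = 154,
              "1010" = 10, "1001" = 28, "1110" = 8, "1011" = 5,
              "1111" = 0, "0000" = 4575)
  tally <- tally_from_classes(counts, n = 77, convention = "paper-n2")
  list(tally = tally, classes = class_counts(tally))
}

#' Dyad-level class distribution of a cell distribution
#'
#' Inverts the representative-orientation counting convention: an unordered
#' dyad falls in an asymmetric class with probability `2 p(representative)`
#' (either orientation) and in a symmetric class with probability
#' `p(representative)`.
#'
#' @param dist A mirror-symmetric `cell_distribution`.
#' @return A tibble with columns `class`, `symmetric` and `prob` (sums
#'   to 1).
#' @export
dyad_distribution <- function(dist) {
  p <- dist_prob(dist)
  if (max(abs(p - p[mirror_state(names(p))])) > 1e-9) {
    stop("distribution is not mirror-symmetric; no dyad-level reduction")
  }
  cl <- linkage_classes()
  tibble(class = cl$class, symmetric = cl$symmetric,
         prob = unname(p[cl$class]) * ifelse(cl$symmetric, 1, 2))
}

# Build the generating model from base rates and an ordered tilt list.
build_generator_model <- function(p_a, p_b, tilts) {
  d <- independence_distribution(p_a, p_b)
  lambdas <- numeric(0)
  for (t in tilts) {
    f <- t$constraint
    if (is.function(f)) f <- f(d, NULL)
    stopifnot(inherits(f, "constraint_function"))
    d <- tilt_distribution(d, f, t$lambda)
    lambdas <- c(lambdas, t$lambda)
  }
  list(dist = d, lambdas = lambdas)
}

#' Sample a pair of directed binary networks
#'
#' Builds the model distribution (independence base, then the given
#' exponential tilts in order), reduces it to the dyad-level class
#' distribution, samples each of the `n(n-1)/2` unordered dyads
#' independently, and assigns a fair-coin orientation to dyads landing in
#' asymmetric classes. Fully reproducible given `seed`.
#'
#' @param n Node count (>= 2).
#' @param p_a,p_b Base per-direction edge rates.
#' @param tilts Ordered list of tilts, each `list(constraint = , lambda = )`
#'   where `constraint` is a [constraint_function()] or a builder
#'   `function(dist, tally)` evaluated against the model built so far.
#' @param seed Integer seed (required: no implicit entropy).
#' @return A list with `edges_a`, `edges_b` (tibbles `from`, `to`), `nodes`
#'   (character vector `d001`, ...), `model` (the generating
#'   `cell_distribution`) and `config` (echo of the arguments).
#' @examples
#' nets <- sample_networks(20, 0.05, 0.1, seed = 1)
#' nrow(nets$edges_a)
#' @export
sample_networks <- function(n, p_a, p_b, tilts = list(), seed) {
  stopifnot(n >= 2, !missing(seed))
  gen <- build_generator_model(p_a, p_b, tilts)
  dd <- dyad_distribution(gen$dist)
  nodes <- sprintf("d%03d", seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)

  withr::local_seed(seed)
  cls <- sample.int(10L, nrow(pairs), replace = TRUE, prob = dd$prob)
  flip <- runif(nrow(pairs)) < 0.5  # orientation coin for asymmetric classes

  cl <- linkage_classes()
  sym <- cl$symmetric[cls]
  swap <- !sym & flip
  src <- ifelse(swap, pairs[, 2], pairs[, 1])
  tgt <- ifelse(swap, pairs[, 1], pairs[, 2])
  bits <- as.matrix(cl[cls, c("x1", "x2", "x3", "x4")])

  edge_tbl <- function(fwd, rev) {
    tibble(
      from = c(nodes[src[fwd == 1]], nodes[tgt[rev == 1]]),
      to = c(nodes[tgt[fwd == 1]], nodes[src[rev == 1]])
    )
  }
  list(
    edges_a = edge_tbl(bits[, 1], bits[, 2]),
    edges_b = edge_tbl(bits[, 3], bits[, 4]),
    nodes = nodes,
    model = gen$dist,
    config = list(n = n, p_a = p_a, p_b = p_b,
                  lambdas = gen$lambdas, seed = seed)
  )
}

#' Reconstruct a pair of networks realizing given class counts
#'
#' Deterministically places each class's dyads on consecutive node pairs so
#' that re-tallying the returned networks reproduces the class counts
#' exactly (used to turn a pre-tabulated census back into concrete
#' networks).
#'
#' @param class_counts Named counts for the 10 class representatives at
#'   dyad level (asymmetric classes: number of dyads in either
#'   orientation; symmetric: number of dyads).
#' @param n Node count; `n(n-1)/2` must be at least the total dyad count.
#' @return A list with `edges_a`, `edges_b` and `nodes`.
#' @export
networks_from_classes <- function(class_counts, n) {
  cl <- linkage_classes()
  stopifnot(setequal(names(class_counts), cl$class))
  total <- sum(class_counts)
  if (total > n * (n - 1) / 2) stop("more dyads than n supports")
  nodes <- sprintf("d%03d", seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  cls <- rep(match(names(class_counts), cl$class),
             times = as.integer(class_counts))
  k <- length(cls)
  bits <- as.matrix(cl[cls, c("x1", "x2", "x3", "x4")])
  src <- nodes[pairs[seq_len(k), 1]]
  tgt <- nodes[pairs[seq_len(k), 2]]
  list(
    edges_a = tibble(
      from = c(src[bits[, 1] == 1], tgt[bits[, 2] == 1]),
      to = c(tgt[bits[, 1] == 1], src[bits[, 2] == 1])),
    edges_b = tibble(
      from = c(src[bits[, 3] == 1], tgt[bits[, 4] == 1]),
      to = c(tgt[bits[, 3] == 1], src[bits[, 4] == 1])),
    nodes = nodes
  )
}

#' Parameter-recovery experiment for the sequential fit
#'
#' Samples paired networks from a known sequentially-tilted model, tallies
#' them under the `offdiag` convention (the generator never samples the
#' diagonal), refits the same constraint sequence without the stopping
#' rule, and reports estimated against generating multipliers.
#'
#' @param n Node count per replicate.
#' @param p_a,p_b Base rates of the generating model.
#' @param tilts Generating tilts as in [sample_networks()].
#' @param constraints Constraint sequence for the refit (defaults to the
#'   registered names matching the shipped builders); must mirror the
#'   generating tilts' functional forms for the estimates to be
#'   comparable.
#' @param seeds Integer vector of seeds, one replicate each.
#' @return A tibble with one row per seed and multiplier: `seed`, `term`,
#'   `true_lambda`, `estimate`, `abs_error`, `dyads`.
#' @examples
#' rec <- recovery_experiment(
#'   n = 120, p_a = 0.05, p_b = 0.1,
#'   tilts = list(list(constraint = function(d, t) {
#'     f_reciprocity("A", sum(d$prob * d$x1))
#'   }, lambda = 1)),
#'   constraints = "f1", seeds = 1
#' )
#' rec$abs_error < 0.5
#' @export
recovery_experiment <- function(n, p_a, p_b, tilts,
                                constraints = c("f1", "f2", "f3", "f4")[seq_along(tilts)],
                                seeds = 1:3) {
  purrr::map_dfr(seeds, function(s) {
    nets <- sample_networks(n, p_a, p_b, tilts, seed = s)
    tally <- linkage_tally(nets$edges_a, nets$edges_b, nodes = nets$nodes,
                           node_policy = "explicit", convention = "offdiag")
    fit <- maxent_fit(tally, constraints = constraints, stop_rule = FALSE)
    est <- tidy(fit)
    tibble(seed = s, term = est$term,
           true_lambda = nets$config$lambdas,
           estimate = est$lambda,
           abs_error = abs(est$lambda - nets$config$lambdas),
           dyads = n * (n - 1) / 2)
  })
}
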