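# Synthetic dyad generator and parameter-recovery plumbing.

test_that("dyad-level class distribution inverts representative counting", {
  # uniform over the 16 states: asymmetric classes get 2/16, symmetric 1/16
  u <- cell_distribution(rep(1 / 16, 16))
  dd <- dyad_distribution(u)
  expect_equal(sum(dd$prob), 1)
  expect_equal(dd$prob[dd$symmetric], rep(1 / 16, 4))
  expect_equal(dd$prob[!dd$symmetric], rep(2 / 16, 6))
  # degenerate: empty networks
  dd0 <- dyad_distribution(independence_distribution(0, 0))
  expect_equal(dd0$prob[dd0$class == "0000"], 1)
  # brute-force enumeration over both orientations of each class
  set.seed(3)
  d <- random_mirror_distribution()
  p <- setNames(d$prob, d$state)
  dd <- dyad_distribution(d)
  cl <- linkage_classes()
  brute <- vapply(seq_len(10), function(k) {
    if (cl$symmetric[k]) p[[cl$class[k]]]
    else p[[cl$class[k]]] + p[[cl$mirror[k]]]
  }, 0)
  expect_equal(dd$prob, unname(brute))
  # non-mirror-symmetric input is rejected
  skew <- setNames(d$prob, d$state)
  skew[["1000"]] <- skew[["1000"]] + 0.02
  skew <- skew / sum(skew)
  expect_error(dyad_distribution(cell_distribution(skew)), "mirror")
})

test_that("sampling is seed-reproducible and hits its class frequencies", {
  n <- 180
  tilts <- list(list(constraint = function(d, t) f_opposition(),
                     lambda = 0.8))
  s1 <- sample_networks(n, 0.05, 0.1, tilts, seed = 101)
  s2 <- sample_networks(n, 0.05, 0.1, tilts, seed = 101)
  expect_identical(s1$edges_a, s2$edges_a)
  expect_identical(s1$edges_b, s2$edges_b)
  s3 <- sample_networks(n, 0.05, 0.1, tilts, seed = 102)
  expect_false(identical(s1$edges_a, s3$edges_a))

  tally <- linkage_tally(s1$edges_a, s1$edges_b, nodes = s1$nodes,
                         node_policy = "explicit", convention = "offdiag")
  expect_equal(sum(tally$count), n * (n - 1))
  # multinomial check: class frequencies within 4 SE of the generator's
  dd <- dyad_distribution(s1$model)
  n_dyads <- n * (n - 1) / 2
  obs <- dyad_counts(tally)
  for (k in seq_len(10)) {
    se <- sqrt(n_dyads * dd$prob[k] * (1 - dd$prob[k]))
    expect_lt(abs(obs[[dd$class[k]]] - n_dyads * dd$prob[k]),
              4 * se + 1e-9)
  }
  # realized density of A within 4 Monte-Carlo SE of the model edge rate
  rate_a <- sum(s1$model$prob * s1$model$x1)
  se_a <- sqrt(rate_a * (1 - rate_a) / (n * (n - 1)))
  expect_lt(abs(nrow(s1$edges_a) / (n * (n - 1)) - rate_a), 4 * se_a)
})

test_that("the packaged census fixture carries its documented counts", {
  fx <- table1_fixture()
  expect_equal(fx$classes$observed, fixture_observed)
  expect_equal(sum(fx$tally$count), 5929)
  expect_equal(edge_totals(fx$tally)$edges[1], 187)
  expect_equal(sum(dyad_counts(fx$tally)), 77 * 76 / 2)
})

test_that("multipliers are recovered from synthetic data", {
  # null truth: estimates near zero
  rec0 <- recovery_experiment(
    n = 500, p_a = 0.05, p_b = 0.1,
    tilts = list(list(constraint = function(d, t) {
      f_reciprocity("A", sum(d$prob * d$x1))
    }, lambda = 0)),
    constraints = "f1", seeds = 1:2
  )
  expect_true(all(abs(rec0$estimate) < 0.1))
  expect_equal(unique(rec0$dyads), 500 * 499 / 2)
  # doubling n shrinks the median absolute error
  tilts <- list(list(constraint = function(d, t) {
    f_reciprocity("A", sum(d$prob * d$x1))
  }, lambda = 1))
  rec_small <- recovery_experiment(n = 100, p_a = 0.05, p_b = 0.1,
                                   tilts = tilts, constraints = "f1",
                                   seeds = 1:3)
  rec_large <- recovery_experiment(n = 200, p_a = 0.05, p_b = 0.1,
                                   tilts = tilts, constraints = "f1",
                                   seeds = 1:3)
  expect_lt(median(rec_large$abs_error), median(rec_small$abs_error))
})

test_that("refit centering induces a small, bounded asymptotic bias", {
  # infinite-data limit: feed the generating model's expected ordered-cell
  # counts straight back as a census; the refit re-derives its centering
  # rate from these "data", so the estimate sits slightly below the
  # generating multiplier rather than exactly on it
  d <- independence_distribution(0.05, 0.1)
  f <- f_reciprocity("A", sum(d$prob * d$x1))
  gen <- tilt_distribution(d, f, 1.0)
  tally <- dyadmaxent:::new_linkage_tally(
    setNames(gen$prob * 1e6, gen$state), n = 1001, convention = "offdiag")
  fit <- maxent_fit(tally, constraints = "f1", stop_rule = FALSE)
  lam_hat <- tidy(fit)$lambda
  expect_gt(lam_hat, 0.9)
  expect_lt(lam_hat, 1.0)
})

test_that("deterministic dyad placement respects capacity limits", {
  counts <- setNames(c(3, 1, 2, 0, 0, 0, 0, 0, 0, 0),
                     linkage_classes()$class)
  expect_error(networks_from_classes(counts, n = 3), "more dyads")
  nets <- networks_from_classes(counts, n = 4)
  tl <- linkage_tally(nets$edges_a, nets$edges_b, nodes = nets$nodes,
                      node_policy = "explicit", convention = "dyad")
  cc <- class_counts(tl)
  expect_equal(cc$observed[cc$class == "1000"], 3L)
  expect_equal(cc$observed[cc$class == "1100"], 1L)
  expect_equal(cc$observed[cc$class == "0010"], 2L)
})
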