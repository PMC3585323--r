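# The method core: independence null, exponential tilting, multiplier
# solving, and the sequential accommodation procedure.

test_that("independence null reproduces the reference expected counts", {
  tally <- fixture_tally()
  r <- edge_rates(tally)$rate
  d0 <- independence_distribution(r[1], r[2])
  E <- expected_class_counts(d0, tally_cells(tally))
  ev <- setNames(E$expected, E$class)
  expect_equal(round(unname(ev["0000"]), 2), 4416.80)
  expect_equal(round(unname(ev["1100"]), 2), 4.68)
  expect_equal(round(unname(ev["1000"]), 2), 143.84)
  expect_equal(sum(d0$prob), 1, tolerance = 1e-14)
  # degenerate rates put all mass on the empty state
  d_empty <- independence_distribution(0, 0)
  expect_equal(d_empty$prob[d_empty$state == "0000"], 1)
})

test_that("empirical means match direct-summation oracles on the census", {
  tally <- fixture_tally()
  f1 <- f_reciprocity("A", 187 / 5929)
  v <- setNames(f1$value, f1$state)
  oracle <- sum(tally$count * v[tally$state]) / 5929
  expect_equal(empirical_mean(f1, tally), oracle)
  expect_equal(empirical_mean(f1, tally), 0.006427, tolerance = 1e-3)
  # opposition: (counts(1001) + counts(0110) - counts(1010) - counts(0101))/N
  expect_equal(empirical_mean(f_opposition(), tally), (56 - 20) / 5929)
})

test_that("tilting behaves algebraically", {
  d <- independence_distribution(0.1, 0.2)
  f3 <- f_opposition()
  # identity at lambda 0
  t0 <- tilt_distribution(d, f3, 0)
  expect_equal(t0$prob, d$prob)
  expect_equal(attr(t0, "partition"), 1)
  # constants are absorbed into the partition value
  fc <- constraint_function("const", rep(2, 16))
  tc <- tilt_distribution(d, fc, 1.3)
  expect_equal(tc$prob, d$prob, tolerance = 1e-14)
  expect_equal(attr(tc, "partition"), exp(2 * 1.3))
  # cell ratio identity: tilting by f3 scales p(1001)/p(1010) by e^{2 lambda}
  lam <- 0.7
  tl <- tilt_distribution(d, f3, lam)
  p0 <- setNames(d$prob, d$state); p1 <- setNames(tl$prob, tl$state)
  expect_equal(p1[["1001"]] / p1[["1010"]],
               exp(2 * lam) * p0[["1001"]] / p0[["1010"]],
               tolerance = 1e-12)
  # mirror symmetry preserved, large multipliers do not overflow
  big <- tilt_distribution(d, f3, 500)
  expect_true(all(is.finite(big$prob)))
  bp <- setNames(big$prob, big$state)
  expect_equal(unname(bp), unname(bp[mirror_state(names(bp))]))
})

test_that("solve_lambda agrees with a grid + uniroot brute-force oracle", {
  set.seed(11)
  for (rep in 1:6) {
    d <- random_mirror_distribution()
    f <- list(f_reciprocity("A", runif(1, 0.05, 0.5)),
              f_opposition(),
              f_presence_covariance(runif(1), runif(1)))[[1 + rep %% 3]]
    v <- setNames(f$value, f$state)
    # pick an attainable target via a random reference tilt
    target <- oracle_tilted_mean(d$prob, unname(v[d$state]),
                                 runif(1, -2, 2))
    lam <- solve_lambda(d, f, target)
    lam_oracle <- oracle_lambda(d$prob, unname(v[d$state]), target)
    expect_equal(lam, lam_oracle, tolerance = 1e-6)
    # moment actually matched
    expect_lt(abs(model_mean(f, tilt_distribution(d, f, lam)) - target), 1e-9)
  }
})

test_that("solve_lambda rejects unattainable targets and degenerate f", {
  d <- independence_distribution(0.1, 0.2)
  f3 <- f_opposition()
  expect_equal(solve_lambda(d, f3, model_mean(f3, d)), 0, tolerance = 1e-9)
  expect_error(solve_lambda(d, f3, 1.5), "attainable")
  expect_error(solve_lambda(d, constraint_function("const", rep(1, 16)), 0.5),
               "degenerate")
})

test_that("single-constraint tilt is the KL projection onto the moment set", {
  set.seed(23)
  for (rep in 1:4) {
    d <- random_mirror_distribution()
    f <- if (rep %% 2) f_opposition() else f_reciprocity("A", 0.3)
    v <- unname(setNames(f$value, f$state)[d$state])
    target <- oracle_tilted_mean(d$prob, v, runif(1, -1, 1))
    lam <- solve_lambda(d, f, target)
    fitted <- tilt_distribution(d, f, lam)
    q_oracle <- oracle_kl_projection(d$prob, v, target)
    expect_equal(kl_div(fitted$prob, d$prob), kl_div(q_oracle, d$prob),
                 tolerance = 1e-5)
  }
})

test_that("chi-squared machinery handles totals, zeros, critical values", {
  tally <- fixture_tally()
  obs <- class_counts(tally)
  r <- edge_rates(tally)$rate
  E <- expected_class_counts(independence_distribution(r[1], r[2]), 5929)
  tab <- chisq_table(obs, E)
  expect_equal(chisq_total(tab), 383.2001, tolerance = 1e-4)
  cell <- tab$chisq[tab$class == "1100"]
  expect_equal(round(cell, 2), 116.04)
  # O = E everywhere -> 0
  same <- suppressWarnings(
    chisq_table(obs, setNames(obs[c("class", "observed")],
                              c("class", "expected"))))
  expect_equal(chisq_total(same), 0)
  # zero-expected handling
  E0 <- E; E0$expected[E0$class == "1111"] <- 0
  expect_warning(chisq_table(obs, E0), "excluded")
  E0$expected[E0$class == "1000"] <- 0
  expect_error(chisq_table(obs, E0), "1000")
  # stopping-rule critical values
  expect_equal(round(critical_value(9, 0.95), 3), 16.919)
  expect_equal(round(critical_value(9, 0.99), 3), 21.666)
  expect_true(critical_value(9, 0.99) > critical_value(9, 0.95))
  expect_true(critical_value(10, 0.95) > critical_value(9, 0.95))
  expect_error(critical_value(9, 1.2), "level")
})

test_that("sequential accommodation is moment-matched and monotone here", {
  fit <- maxent_fit(fixture_tally(), centering = "paper-table-1-compat")
  totals <- unname(fit_totals(fit))
  expect_equal(length(totals), 5)
  expect_true(all(diff(totals) < 0))
  est <- tidy(fit)
  # each step matches its own empirical moment
  for (k in seq_len(nrow(est))) {
    f <- fit$steps[[k + 1]]$fitted$constraint
    expect_lt(abs(model_mean(f, fit_distribution(fit, k)) -
                    est$empirical_mean[k]), 1e-8)
  }
  # f1's moment survives the f2 tilt (disjoint blocks)
  f1 <- fit$steps[[2]]$fitted$constraint
  expect_lt(abs(model_mean(f1, fit_distribution(fit, 2)) -
                  est$empirical_mean[1]), 1e-10)
  # mean-zero diagnostics: f2 under post-f1 and f3 under post-f2 vanish
  expect_lt(abs(est$mean_zero_deviation[2]), 1e-12)
  expect_lt(abs(est$mean_zero_deviation[3]), 1e-12)
  # f4's current-model mean is a small, reported covariance
  expect_gt(abs(est$mean_zero_deviation[4]), 0)
  expect_lt(abs(est$mean_zero_deviation[4]), 0.05)
  # every model along the way normalizes and stays mirror-symmetric
  for (s in fit$steps) {
    p <- setNames(s$dist$prob, s$dist$state)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(unname(p), unname(p[mirror_state(names(p))]),
                 tolerance = 1e-12)
  }
})

test_that("a census drawn from the independence model stops at step 0", {
  d <- independence_distribution(0.05, 0.1)
  counts <- round(d$prob * 2e5)
  tally <- dyadmaxent:::new_linkage_tally(counts, n = 450,
                                          convention = "offdiag")
  fit <- maxent_fit(tally, constraints = c("f1", "f2"))
  expect_lt(fit$steps[[1]]$total, fit$critical)
  expect_equal(length(fit$steps), 1L)
  expect_true(fit$stopped_early)
  expect_true(fit$converged)
})

test_that("joint refitting matches all moments simultaneously", {
  fit <- maxent_fit(fixture_tally(), refit = "joint", stop_rule = FALSE)
  final <- fit_distribution(fit)
  est <- tidy(fit)
  for (k in seq_len(nrow(est))) {
    f <- fit$steps[[k + 1]]$fitted$constraint
    expect_lt(abs(model_mean(f, final) - est$empirical_mean[k]), 1e-8)
  }
  # the greedy fit only guarantees the most recent moment; joint must do
  # at least as well on the earliest one
  seq_fit <- maxent_fit(fixture_tally(), stop_rule = FALSE)
  f1 <- seq_fit$steps[[2]]$fitted$constraint
  seq_err <- abs(model_mean(f1, fit_distribution(seq_fit)) -
                   tidy(seq_fit)$empirical_mean[1])
  joint_err <- abs(model_mean(fit$steps[[2]]$fitted$constraint, final) -
                     est$empirical_mean[1])
  expect_lte(joint_err, seq_err + 1e-10)
  # simultaneous matching can only improve the overall fit here
  expect_lte(fit_totals(fit)[["f4"]], fit_totals(seq_fit)[["f4"]] + 1e-8)
})

test_that("fit accessors validate their inputs", {
  fit <- maxent_fit(fixture_tally())
  expect_error(fit_distribution(fit, "nope"), "no such step")
  expect_s3_class(fit_distribution(fit, "indep"), "cell_distribution")
  expect_error(maxent_fit(fixture_tally(), constraints = "bogus"), "unknown")
  expect_error(maxent_fit(fixture_tally(), constraints = list()), "at least")
})
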