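# Independent oracles and small generators used across the suite. They stay
# deliberately naive: direct summation, grid/uniroot root search, and a
# generic penalized simplex optimizer, none sharing code with the package's
# solver path.

state_bits <- function() {
  st <- linkage_states()
  as.matrix(st[, c("x1", "x2", "x3", "x4")])
}

# tilted mean computed from first principles
oracle_tilted_mean <- function(p, f, lambda) {
  w <- p * exp(lambda * f)
  sum(w * f) / sum(w)
}

# brute-force multiplier: coarse grid scan then uniroot refinement
oracle_lambda <- function(p, f, target, lim = 10) {
  grid <- seq(-lim, lim, length.out = 2001)
  m <- vapply(grid, function(l) oracle_tilted_mean(p, f, l), 0)
  k <- which(diff(sign(m - target)) != 0)[1]
  stopifnot(!is.na(k))
  uniroot(function(l) oracle_tilted_mean(p, f, l) - target,
          c(grid[k], grid[k + 1]), tol = 1e-12)$root
}

kl_div <- function(q, p) {
  keep <- q > 0
  sum(q[keep] * log(q[keep] / p[keep]))
}

# generic constrained KL minimizer over the 16-simplex: softmax
# parameterization with an augmented-Lagrangian treatment of the equality
# moment constraint (generic BFGS inner solves, multiplier updates outer)
oracle_kl_projection <- function(p, f, target, pen = 1e4, outer = 12) {
  theta <- log(p + 1e-12)
  mu <- 0
  softmax <- function(th) { q <- exp(th - max(th)); q / sum(q) }
  for (k in seq_len(outer)) {
    obj <- function(th) {
      q <- softmax(th)
      g <- sum(q * f) - target
      kl_div(q, p) + mu * g + pen / 2 * g^2
    }
    theta <- optim(theta, obj, method = "BFGS",
                   control = list(maxit = 5000, reltol = 1e-15))$par
    violation <- sum(softmax(theta) * f) - target
    if (abs(violation) < 1e-10) break
    mu <- mu + pen * violation
  }
  softmax(theta)
}

# random mirror-symmetric distribution with full support
random_mirror_distribution <- function() {
  st <- linkage_states()
  w <- stats::rgamma(16, shape = 2)
  w <- (w + w[match(st$mirror, st$state)]) / 2
  cell_distribution(setNames(w / sum(w), st$state))
}

# random pair of directed binary networks on n named nodes
random_network_pair <- function(n, p_a = 0.1, p_b = 0.15) {
  nodes <- sprintf("v%02d", seq_len(n))
  all_pairs <- expand.grid(from = nodes, to = nodes,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
  list(
    edges_a = tibble::as_tibble(all_pairs[runif(nrow(all_pairs)) < p_a, ]),
    edges_b = tibble::as_tibble(all_pairs[runif(nrow(all_pairs)) < p_b, ]),
    nodes = nodes
  )
}

fixture_tally <- function() table1_fixture()$tally

# Observed class counts printed in the reference census, canonical order
fixture_observed <- c(100, 28, 435, 154, 10, 28, 8, 5, 0, 4575)
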