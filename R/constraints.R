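# Constraint functions: real-valued functions on the 16 linkage states that
# encode an association absent from the current model. Each is accommodated
# by one exponential tilt whose multiplier is moment-matched to the data.
# All shipped constraints are mirror-invariant, so tilting preserves the
# mirror symmetry of the model.

#' Build a constraint function from 16 values
#'
#' @param name Label used in reports and model files.
#' @param values Numeric vector of 16 finite values, named by state or in
#'   the canonical state order of [linkage_states()].
#' @param centering Named list of constants used in the construction (kept
#'   for provenance and serialization).
#' @return A `constraint_function`: a tibble (`state`, `value`) with
#'   attributes `name` and `centering`.
#' @export
constraint_function <- function(name, values, centering = list()) {
  if (!is.null(names(values))) {
    values <- values[.state_space$state]
    if (anyNA(values)) stop("`values` must cover all 16 states")
  }
  stopifnot(length(values) == 16, all(is.finite(values)))
  out <- tibble(state = .state_space$state, value = unname(values))
  structure(out, name = name, centering = centering,
            class = c("constraint_function", class(out)))
}

constraint_values <- function(f) {
  stopifnot(inherits(f, "constraint_function"))
  setNames(f$value, f$state)
}

constraint_name <- function(f) attr(f, "name")

#' @export
print.constraint_function <- function(x, ...) {
  cat(sprintf("<constraint_function '%s'>\n", attr(x, "name")))
  NextMethod()
}

#' Within-network reciprocity constraint
#'
#' The centered product of a network's two direction indicators:
#' `(x1 - rate)(x2 - rate)` for network A, `(x3 - rate)(x4 - rate)` for B.
#' Positive weight on mutual and mutually-absent edges, negative on one-way
#' edges; exactly mean-zero under any model in which the network's two
#' directions are independent with marginal `rate`. Tilting by it raises
#' (for positive multiplier) the probability of reciprocated interaction.
#'
#' @param network `"A"` or `"B"`.
#' @param rate Centering rate in (0, 1), normally the current model's
#'   per-direction edge rate for that network.
#' @return A `constraint_function` (named `f1` for A, `f2` for B).
#' @export
f_reciprocity <- function(network = c("A", "B"), rate) {
  network <- match.arg(network)
  stopifnot(rate > 0, rate < 1)
  st <- .state_space
  v <- if (network == "A") (st$x1 - rate) * (st$x2 - rate)
       else (st$x3 - rate) * (st$x4 - rate)
  constraint_function(if (network == "A") "f1" else "f2",
                      setNames(v, st$state),
                      centering = list(network = network, rate = rate))
}

#' Cross-network direction-opposition constraint
#'
#' `(x1 - x2)(x4 - x3)`: equals +1 exactly on the two states where one-way
#' edges of the two networks point in opposite directions (`1001`, `0110`),
#' -1 where they point the same way (`1010`, `0101`), and 0 elsewhere. A
#' positive multiplier shifts probability from same-direction to
#' opposite-direction one-way pairs, leaving their sum's tendency intact.
#'
#' @return A `constraint_function` named `f3`.
#' @export
f_opposition <- function() {
  st <- .state_space
  v <- (st$x1 - st$x2) * (st$x4 - st$x3)
  constraint_function("f3", setNames(v, st$state))
}

#' Cross-network presence-covariance constraint
#'
#' `(max(x1, x2) - a)(max(x3, x4) - b)`: the centered product of the "any
#' edge in A" and "any edge in B" indicators of a cell. Positive where both
#' behaviors are present or both absent, negative where exactly one is
#' present, so a positive multiplier moves probability toward co-occurrence
#' of the two behaviors on a pair.
#'
#' @param a,b Centering constants in `[0, 1]` for the any-A and any-B
#'   indicators (see [maxent_fit()] for the two shipped centering policies).
#' @return A `constraint_function` named `f4`.
#' @export
f_presence_covariance <- function(a, b) {
  stopifnot(a >= 0, a <= 1, b >= 0, b <= 1)
  st <- .state_space
  v <- (pmax(st$x1, st$x2) - a) * (pmax(st$x3, st$x4) - b)
  constraint_function("f4", setNames(v, st$state),
                      centering = list(a = a, b = b))
}

# Builders used by the sequential fit: each takes the CURRENT model and the
# tally and returns a constraint whose centering constants are drawn from
# current-model quantities (or, for the "paper-table-1-compat" policy of f4,
# from an empirical cell frequency).
constraint_builders <- function(centering = c("model", "paper-table-1-compat")) {
  centering <- match.arg(centering)
  list(
    f1 = function(dist, tally) {
      f_reciprocity("A", rate = sum(dist$prob * dist$x1))
    },
    f2 = function(dist, tally) {
      f_reciprocity("B", rate = sum(dist$prob * dist$x3))
    },
    f3 = function(dist, tally) f_opposition(),
    f4 = function(dist, tally) {
      a <- sum(dist$prob * pmax(dist$x1, dist$x2))
      b <- if (centering == "model") {
        sum(dist$prob * pmax(dist$x3, dist$x4))
      } else {
        # one-way-B-only cell frequency (both orientations) in the data
        cnt <- setNames(tally$count, tally$state)
        (cnt[["0010"]] + cnt[["0001"]]) / tally_cells(tally)
      }
      f_presence_covariance(a, b)
    }
  )
}

resolve_constraints <- function(constraints, centering) {
  builders <- constraint_builders(centering)
  out <- lapply(seq_along(constraints), function(k) {
    ck <- constraints[[k]]
    if (is.character(ck)) {
      b <- builders[[ck]]
      if (is.null(b)) {
        stop("unknown constraint name '", ck, "'; registered: ",
             paste(names(builders), collapse = ", "))
      }
      b
    } else if (is.function(ck)) {
      ck
    } else if (inherits(ck, "constraint_function")) {
      function(dist, tally) ck
    } else {
      stop("constraints must be registered names, builder functions, or ",
           "constraint_function objects")
    }
  })
  names(out) <- vapply(seq_along(constraints), function(k) {
    if (is.character(constraints[[k]])) constraints[[k]]
    else if (inherits(constraints[[k]], "constraint_function"))
      constraint_name(constraints[[k]])
    else sprintf("custom_%d", k)
  }, "")
  out
}
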