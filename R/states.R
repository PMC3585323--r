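# Linkage-state space: each ordered node pair (i, j) in a two-network system
# carries a 4-bit code (x1, x2, x3, x4) = (A i->j, A j->i, B i->j, B j->i).
# Swapping the roles of i and j maps a state to its "mirror" (x2, x1, x4, x3);
# the 16 states therefore collapse to 10 mirror-equivalence classes.

# Class representatives in the row order used throughout reports: one-way A,
# mutual A, one-way B, mutual B, same-direction A+B, opposite-direction A+B,
# mutual A + one-way B, one-way A + mutual B, everything, nothing.
.class_order <- c(
  "1000", "1100", "0010", "0011", "1010",
  "1001", "1110", "1011", "1111", "0000"
)

.state_space <- local({
  grid <- expand.grid(x4 = 0:1, x3 = 0:1, x2 = 0:1, x1 = 0:1,
                      KEEP.OUT.ATTRS = FALSE)[, 4:1]
  state <- apply(grid, 1, paste, collapse = "")
  mirror <- paste0(substr(state, 2, 2), substr(state, 1, 1),
                   substr(state, 4, 4), substr(state, 3, 3))
  rep <- ifelse(state >= mirror, state, mirror)
  data.frame(state = state, grid, mirror = mirror, class = rep,
             symmetric = state == mirror, stringsAsFactors = FALSE)
})

#' The 16 linkage states of a two-network dyad code
#'
#' Every ordered node pair in a pair of directed binary networks A and B is
#' encoded by four indicators `(x1, x2, x3, x4)`: `x1` marks an A-edge from
#' the first node to the second, `x2` the reverse A-edge, and `x3`, `x4` the
#' same for network B. This function enumerates all 16 states together with
#' their mirror image (the code obtained by reading the pair in the other
#' order) and the mirror-equivalence class each state belongs to.
#'
#' @return A tibble with one row per state and columns `state` (4-character
#'   binary string), `x1`..`x4` (0/1 integers), `mirror` (the state read in
#'   the opposite pair order), `class` (the class representative, the
#'   lexicographically larger of the state and its mirror), and `symmetric`
#'   (`TRUE` when the state is its own mirror).
#' @examples
#' linkage_states()
#' @export
linkage_states <- function() {
  as_tibble(.state_space)
}

#' Mirror a linkage state
#'
#' Reading an ordered pair (i, j) in the opposite order (j, i) swaps the two
#' directions within each network: `(x1, x2, x3, x4)` becomes
#' `(x2, x1, x4, x3)`. The operation is an involution.
#'
#' @param state Character vector of 4-character binary strings, e.g. `"1001"`.
#' @return Character vector of mirrored states.
#' @examples
#' mirror_state(c("1001", "1100"))
#' @export
mirror_state <- function(state) {
  stopifnot(is.character(state), all(grepl("^[01]{4}$", state)))
  paste0(substr(state, 2, 2), substr(state, 1, 1),
         substr(state, 4, 4), substr(state, 3, 3))
}

#' The 10 mirror-equivalence classes of linkage states
#'
#' Because the two orderings of a dyad describe the same pair of animals, a
#' state and its mirror are the same biological configuration; the 16 states
#' collapse to 10 distinct classes. Four classes (`0000`, `1100`, `0011`,
#' `1111`) are symmetric (their own mirror); the remaining six pair two
#' orientations each.
#'
#' @return A tibble with 10 rows, in the canonical report order, and columns
#'   `class` (representative state), `x1`..`x4` of the representative,
#'   `mirror` (the other orientation), and `symmetric`.
#' @examples
#' linkage_classes()
#' @export
linkage_classes <- function() {
  st <- .state_space
  out <- st[match(.class_order, st$state), c("state", "x1", "x2", "x3", "x4",
                                             "mirror", "symmetric")]
  names(out)[1] <- "class"
  rownames(out) <- NULL
  as_tibble(out)
}
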