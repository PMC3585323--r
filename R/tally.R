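# Dyad census for a pair of directed binary networks: the 16-state linkage
# tally is the sufficient statistic for every model in this package.

#' Tally linkage states over all ordered node pairs
#'
#' Encodes two directed binary networks on a shared node set into counts of
#' the 16 linkage states. Three counting conventions are supported:
#'
#' * `"paper-n2"` (default): all `n^2` ordered cells are tallied, the `n`
#'   diagonal cells counting as the all-zero state. This is the convention
#'   under which the reference grooming/aggression census reproduces exactly.
#' * `"offdiag"`: the `n(n-1)` ordered off-diagonal cells.
#' * `"dyad"`: each of the `n(n-1)/2` unordered dyads once, in the canonical
#'   orientation whose state is the class representative (mirror symmetry of
#'   the counts is therefore not expected under this convention).
#'
#' @param edges_a,edges_b Data frames of directed edges with columns `from`
#'   and `to` (node identifiers, coerced to character). An optional `weight`
#'   column is binarized (`> 0` becomes an edge) with a warning. Self-loops
#'   are dropped with a warning.
#' @param nodes Optional character vector fixing the node set (required for
#'   `node_policy = "explicit"`; isolated nodes are allowed and matter for
#'   the census size).
#' @param node_policy How to resolve the node set: `"union"` (default) or
#'   `"intersection"` of the two networks' endpoint sets, or `"explicit"`
#'   (use `nodes` as given; edges with endpoints outside it are an error).
#' @param convention Counting convention, see above.
#' @return A `linkage_tally`: a tibble with columns `state`, `x1`..`x4` and
#'   `count`, carrying attributes `n` (node count), `convention` and `nodes`.
#' @examples
#' a <- tibble::tibble(from = "m1", to = "m2")
#' b <- tibble::tibble(from = character(), to = character())
#' linkage_tally(a, b, nodes = c("m1", "m2"), node_policy = "explicit")
#' @export
linkage_tally <- function(edges_a, edges_b, nodes = NULL,
                          node_policy = c("union", "intersection", "explicit"),
                          convention = c("paper-n2", "offdiag", "dyad")) {
  node_policy <- match.arg(node_policy)
  convention <- match.arg(convention)
  edges_a <- clean_edges(edges_a, "A")
  edges_b <- clean_edges(edges_b, "B")

  seen <- union(unique(c(edges_a$from, edges_a$to)),
                unique(c(edges_b$from, edges_b$to)))
  nodes <- switch(node_policy,
    union = sort(union(seen, as.character(nodes %||% character()))),
    intersection = sort(intersect(
      unique(c(edges_a$from, edges_a$to)),
      unique(c(edges_b$from, edges_b$to))
    )),
    explicit = {
      if (is.null(nodes)) stop("node_policy = 'explicit' requires `nodes`")
      as.character(nodes)
    }
  )
  if (anyDuplicated(nodes)) stop("duplicated node identifiers in node set")
  n <- length(nodes)
  if (n < 2) stop("need at least 2 nodes to form a dyad")

  if (node_policy == "intersection") {
    edges_a <- edges_a[edges_a$from %in% nodes & edges_a$to %in% nodes, ]
    edges_b <- edges_b[edges_b$from %in% nodes & edges_b$to %in% nodes, ]
  }
  check_endpoints(edges_a, nodes, "A")
  check_endpoints(edges_b, nodes, "B")

  A <- adjacency_from_edges(edges_a, nodes)
  B <- adjacency_from_edges(edges_b, nodes)

  # state index 1..16 from the 4 bits of each ordered cell
  idx <- 8L * A + 4L * t(A) + 2L * B + t(B) + 1L
  keep <- upper.tri(idx) | lower.tri(idx)
  if (convention == "dyad") keep <- lower.tri(idx)  # cell (i, j) with i > j
  tab <- tabulate(idx[keep], nbins = 16L)

  st <- .state_space
  ord <- 8L * st$x1 + 4L * st$x2 + 2L * st$x3 + st$x4 + 1L
  counts <- integer(16)
  counts[seq_len(16)] <- tab[ord]
  if (convention == "paper-n2") {
    counts[st$state == "0000"] <- counts[st$state == "0000"] + n
  }
  if (convention == "dyad") {
    # fold each dyad into the canonical (representative) orientation
    folded <- vapply(seq_len(16), function(k) {
      if (st$state[k] == st$class[k]) {
        counts[k] + if (st$symmetric[k]) 0L else counts[st$state == st$mirror[k]]
      } else 0L
    }, integer(1))
    counts <- folded
  }

  new_linkage_tally(counts, n = n, convention = convention, nodes = nodes)
}

new_linkage_tally <- function(counts, n, convention, nodes = NULL) {
  st <- .state_space
  out <- as_tibble(cbind(st[c("state", "x1", "x2", "x3", "x4")],
                         count = as.integer(counts)))
  structure(out, n = n, convention = convention, nodes = nodes,
            class = c("linkage_tally", class(out)))
}

#' @export
print.linkage_tally <- function(x, ...) {
  cat(sprintf("<linkage_tally> n = %d, convention = %s, cells = %d\n",
              attr(x, "n"), attr(x, "convention"), sum(x$count)))
  NextMethod()
}

#' Total number of census cells of a tally
#'
#' `n^2` under the `paper-n2` convention, `n(n-1)` under `offdiag`,
#' `n(n-1)/2` under `dyad`; always equal to the sum of the 16 state counts.
#'
#' @param tally A [linkage_tally()].
#' @return A single number.
#' @export
tally_cells <- function(tally) {
  stopifnot(inherits(tally, "linkage_tally"))
  sum(tally$count)
}

#' Observed counts per linkage class
#'
#' Collapses a 16-state tally to the 10 mirror-equivalence classes using the
#' representative-orientation convention of the reference census: asymmetric
#' classes report one orientation only (the number of unordered dyads in
#' that configuration), symmetric classes report their full ordered count.
#'
#' @param tally A [linkage_tally()].
#' @return A tibble with columns `class`, `symmetric` and `observed`, in the
#'   canonical class order.
#' @examples
#' fx <- table1_fixture()
#' class_counts(fx$tally)
#' @export
class_counts <- function(tally) {
  stopifnot(inherits(tally, "linkage_tally"))
  cl <- linkage_classes()
  counts <- setNames(tally$count, tally$state)
  cl$observed <- as.integer(counts[cl$class])
  cl[, c("class", "symmetric", "observed")]
}

#' Directed edge totals implied by a tally
#'
#' Sums `count * x1` (network A) and `count * x3` (network B) over the full
#' 16-state tally; for a tally built from networks under an ordered-pair
#' convention this equals each network's literal directed edge count.
#'
#' @param tally A [linkage_tally()].
#' @return A tibble with columns `network` (`"A"`, `"B"`) and `edges`.
#' @export
edge_totals <- function(tally) {
  stopifnot(inherits(tally, "linkage_tally"))
  tibble(network = c("A", "B"),
         edges = c(sum(tally$count * tally$x1), sum(tally$count * tally$x3)))
}

#' Per-direction edge rates (network densities) from a tally
#'
#' Divides each network's implied directed edge total by the tally's total
#' cell count. Under the `paper-n2` convention this is the "edges over all
#' possible edges" density with denominator `n^2`.
#'
#' @param tally A [linkage_tally()].
#' @return A tibble with columns `network`, `edges`, `cells` and `rate`.
#' @examples
#' edge_rates(table1_fixture()$tally)
#' @export
edge_rates <- function(tally) {
  m <- edge_totals(tally)
  N <- tally_cells(tally)
  if (N == 0) stop("tally has zero cells; rates are undefined")
  tibble(network = m$network, edges = m$edges, cells = N, rate = m$edges / N)
}

#' Write / read a linkage tally as JSON
#'
#' The JSON object stores `n`, `convention` and all 16 state counts and
#' round-trips exactly.
#'
#' @param tally A [linkage_tally()].
#' @param path File path.
#' @return `write_tally_json()` returns `path` invisibly; `read_tally_json()`
#'   returns a [linkage_tally()].
#' @export
write_tally_json <- function(tally, path) {
  stopifnot(inherits(tally, "linkage_tally"))
  obj <- list(
    n = attr(tally, "n"),
    convention = attr(tally, "convention"),
    counts = as.list(setNames(tally$count, tally$state))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_tally_json
#' @export
read_tally_json <- function(path) {
  obj <- jsonlite::read_json(path)
  counts <- vapply(.state_space$state,
                   function(s) as.integer(obj$counts[[s]] %||% 0L), integer(1))
  new_linkage_tally(counts, n = as.integer(obj$n),
                    convention = as.character(obj$convention))
}

#' Build a tally directly from a named count vector
#'
#' Mostly useful for pre-tabulated censuses: class-level counts are expanded
#' to the 16 states by mirror symmetry (each asymmetric class count is placed
#' on both orientations).
#'
#' @param class_counts Named numeric vector of counts for the 10 class
#'   representatives (names are states such as `"1000"`).
#' @param n Node count.
#' @param convention Counting convention of the stored counts.
#' @return A [linkage_tally()].
#' @export
tally_from_classes <- function(class_counts, n,
                               convention = c("paper-n2", "offdiag", "dyad")) {
  convention <- match.arg(convention)
  cl <- linkage_classes()
  if (!setequal(names(class_counts), cl$class)) {
    stop("`class_counts` must be named by the 10 class representatives")
  }
  st <- .state_space
  counts <- numeric(16)
  for (k in seq_len(nrow(cl))) {
    v <- cl$class[k]
    counts[st$state == v] <- class_counts[[v]]
    if (!cl$symmetric[k] && convention != "dyad") {
      counts[st$state == cl$mirror[k]] <- class_counts[[v]]
    }
  }
  new_linkage_tally(counts, n = n, convention = convention)
}

#' Dyad-level class counts of a tally
#'
#' Converts a tally's state counts to the number of unordered dyads per
#' class: an asymmetric class has one dyad per representative-orientation
#' cell, a symmetric class one dyad per two ordered cells, and under the
#' `paper-n2` convention the `n` diagonal cells are removed from the
#' all-zero class first. The result feeds [networks_from_classes()].
#'
#' @param tally A [linkage_tally()].
#' @return Named numeric vector of dyad counts, one per class
#'   representative, summing to `n(n-1)/2`.
#' @export
dyad_counts <- function(tally) {
  stopifnot(inherits(tally, "linkage_tally"))
  conv <- attr(tally, "convention")
  cl <- linkage_classes()
  counts <- setNames(tally$count, tally$state)[cl$class]
  if (conv == "paper-n2") {
    counts[["0000"]] <- counts[["0000"]] - attr(tally, "n")
  }
  if (conv != "dyad") counts[cl$symmetric] <- counts[cl$symmetric] / 2
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clean_edges <- function(edges, label) {
  stopifnot(is.data.frame(edges))
  if (!all(c("from", "to") %in% names(edges))) {
    stop(sprintf("network %s: edge table needs `from` and `to` columns", label))
  }
  edges <- as.data.frame(edges)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if ("weight" %in% names(edges)) {
    w <- as.numeric(edges$weight)
    if (any(w != (w > 0))) {
      warning(sprintf("network %s: edge weights binarized (> 0 -> edge)", label))
    }
    edges <- edges[w > 0, c("from", "to")]
  } else {
    edges <- edges[, c("from", "to")]
  }
  loops <- edges$from == edges$to
  if (any(loops)) {
    warning(sprintf("network %s: dropped %d self-loop(s)", label, sum(loops)))
    edges <- edges[!loops, ]
  }
  unique(edges)
}

check_endpoints <- function(edges, nodes, label) {
  bad <- !(edges$from %in% nodes) | !(edges$to %in% nodes)
  if (any(bad)) {
    k <- which(bad)[1]
    stop(sprintf("network %s: edge %s -> %s has an endpoint outside the node set",
                 label, edges$from[k], edges$to[k]))
  }
}

adjacency_from_edges <- function(edges, nodes) {
  n <- length(nodes)
  M <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) M[cbind(edges$from, edges$to)] <- 1L
  M
}
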