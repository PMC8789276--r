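#' Bi-partitionability of a degree-regular group
#'
#' For a group in which every cell has the same number of neighbours `d`,
#' computes the bi-partitionability measure `mu`: the largest eigenvalue of
#' the graph Laplacian `L = d I - A`, equivalently `d - a_min` for `a_min`
#' the smallest adjacency eigenvalue. `mu` measures how well the group can
#' be split into two classes whose members neighbour mostly the opposing
#' class; it attains its maximum `2d` exactly for bipartite graphs. The
#' corresponding eigenvector's sign pattern proposes the role assignment
#' that realises the best split, and `d / mu` (never below 1/2) is the
#' shareability threshold of the sparse-network invasion condition.
#'
#' This convention is fixed by consistency with the exact per-cell Hessian
#' of the linear model, whose leading eigenvalue is
#' `-2 (1 - lambda) + (2 lambda / d) (mu - d)`: it is positive exactly when
#' `lambda * mu > d`. It reproduces the alternating-filament threshold
#' `lambda > 1/2` (`mu = 4`, `d = 2`) and the well-mixed threshold
#' `lambda > (n - 1) / n` (`mu = n`, `d = n - 1`).
#'
#' Non-regular graphs are rejected: when neighbour counts vary between
#' cells, division of labour is already favoured at first order by
#' between-individual differences and the spectral condition does not
#' apply.
#'
#' @param graph a d-regular [group_graph()].
#' @return An object of class `spectral_summary` with fields `d`, `mu`,
#'   `lambda_threshold` and `bipartition`.
#' @examples
#' bipartition_measure(filament_graph(6))  # mu = 4, threshold 1/2
#' @export
bipartition_measure <- function(graph) {
  stopifnot(inherits(graph, "group_graph"))
  d <- unique(graph$degrees)
  if (length(d) != 1) {
    off <- which(graph$degrees != stats::median(graph$degrees))
    stop("regularity error: graph is not degree-regular (offending cells: ",
         paste(off - 1L, collapse = ", "), ")", call. = FALSE)
  }
  eig <- eigen(graph$adjacency, symmetric = TRUE)
  a_min <- eig$values[graph$n]
  v <- eig$vectors[, graph$n]
  bip <- if (any(v > 1e-12) && any(v < -1e-12)) {
    ifelse(v > 0, "helper", "reproductive")
  } else {
    ifelse(rank(v, ties.method = "first") > graph$n / 2,
           "helper", "reproductive")
  }
  structure(
    list(d = d, mu = d - a_min, lambda_threshold = d / (d - a_min),
         bipartition = role_assignment(bip)),
    class = "spectral_summary"
  )
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf(
    "spectral_summary: d = %d, mu = %.6g, invasion threshold lambda > %.6g\n",
    x$d, x$mu, x$lambda_threshold))
  invisible(x)
}

#' Sparse-network invasion condition
#'
#' Evaluates the condition `lambda * mu > d` (strict) under which
#' reciprocal specialisation can invade uniform cooperation on a
#' degree-regular group with linear returns: invasion is easier when groups
#' are sparse (low `d`), easily bi-partitioned (high `mu`), or share
#' generously (high `lambda`).
#'
#' @inheritParams bipartition_measure
#' @param lambda shareability in `[0, 1]`.
#' @return `TRUE` or `FALSE`.
#' @export
sparse_condition <- function(graph, lambda) {
  check_lambda(lambda)
  ss <- bipartition_measure(graph)
  # evaluated on the scale of the Hessian's leading eigenvalue,
  # 2 (lambda * mu / d - 1), with the same strictness guard as the
  # brute-force oracle, so the two verdicts agree at the exact boundary
  2 * (lambda * ss$mu / ss$d - 1) > 1e-10
}

#' Brute-force instability oracle for regular graphs
#'
#' Recomputes the invasion verdict without any spectral shortcut: builds
#' the exact `n x n` Hessian of group fitness for the linear model
#' (`-2 (1 - lambda) I - (2 lambda / d) A`) and reports whether its leading
#' eigenvalue is positive. Restricted to small regular graphs
#' (`n <= 14`); agrees with [sparse_condition()] everywhere, which the
#' test suite asserts over a lambda grid.
#'
#' @inheritParams sparse_condition
#' @return `TRUE` or `FALSE`.
#' @export
brute_force_instability <- function(graph, lambda) {
  stopifnot(inherits(graph, "group_graph"))
  if (graph$n > 14) {
    stop("size error: brute-force oracle is restricted to n <= 14",
         call. = FALSE)
  }
  d <- unique(graph$degrees)
  if (length(d) != 1) {
    stop("regularity error: graph is not degree-regular", call. = FALSE)
  }
  fh <- full_hessian(graph, lambda, power_tradeoff(1))
  fh$leading_eigenvalue > 1e-10
}
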