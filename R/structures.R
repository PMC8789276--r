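#' Group graphs: the arena on which public goods flow
#'
#' A `group_graph` is a connected, undirected, simple graph over `n > 2`
#' cells, stored as a dense 0/1 adjacency matrix together with per-cell
#' degrees. It is the topology over which a cell's shared public good is
#' split equally among its direct neighbours.
#'
#' @param adjacency square symmetric 0/1 matrix with empty diagonal.
#' @return An object of class `group_graph` with fields `n`, `adjacency`
#'   and `degrees`.
#' @seealso [filament_graph()], [branching_graph()], [well_mixed_graph()],
#'   [read_edge_list()]
#' @export
group_graph <- function(adjacency) {
  A <- as.matrix(adjacency)
  if (nrow(A) != ncol(A)) {
    stop("adjacency must be a square matrix", call. = FALSE)
  }
  storage.mode(A) <- "double"
  if (anyNA(A) || !all(A %in% c(0, 1))) {
    stop("adjacency entries must be 0 or 1", call. = FALSE)
  }
  if (!isTRUE(all.equal(A, t(A)))) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  if (any(diag(A) != 0)) {
    stop("self-loops are not allowed (non-empty diagonal)", call. = FALSE)
  }
  n <- nrow(A)
  if (n <= 2) {
    stop("a group needs n > 2 cells", call. = FALSE)
  }
  deg <- rowSums(A)
  if (any(deg < 1)) {
    stop("every cell needs at least one neighbour", call. = FALSE)
  }
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  if (!igraph::is_connected(ig)) {
    stop("group graph must be connected", call. = FALSE)
  }
  dimnames(A) <- NULL
  structure(
    list(n = n, adjacency = A, degrees = as.numeric(deg)),
    class = "group_graph"
  )
}

#' @export
print.group_graph <- function(x, ...) {
  dr <- range(x$degrees)
  cat(sprintf(
    "group_graph: %d cells, %d edges, degrees %s\n",
    x$n, sum(x$adjacency) / 2,
    if (dr[1] == dr[2]) sprintf("all %d", dr[1]) else sprintf("%d..%d", dr[1], dr[2])
  ))
  invisible(x)
}

#' Filament (chain) group structure
#'
#' Builds a one-dimensional chain of cells. The default is the periodic
#' chain (a cycle), in which every cell has exactly two neighbours, so the
#' filament is a pure test of reciprocal specialisation: no cell is
#' predisposed to either role by its position. The open chain is available
#' with `periodic = FALSE`, but its end cells have a single neighbour and
#' therefore introduce between-individual differences of the kind the
#' branching structure is designed to study.
#'
#' @param n number of cells, at least 4.
#' @param periodic if `TRUE` (default), close the chain into a cycle.
#' @return A [group_graph()].
#' @examples
#' filament_graph(6)
#' @export
filament_graph <- function(n, periodic = TRUE) {
  if (length(n) != 1 || n != round(n) || n < 4) {
    stop("invalid size: a filament needs an integer n >= 4", call. = FALSE)
  }
  n <- as.integer(n)
  A <- matrix(0, n, n)
  idx <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
  A[idx] <- 1
  A[idx[, 2:1]] <- 1
  if (periodic) {
    A[1, n] <- A[n, 1] <- 1
  }
  group_graph(A)
}

#' Branching group structure
#'
#' Builds a connected group in which cells alternately have two or three
#' neighbours: every "node" cell has degree 3 with all neighbours "edge"
#' cells, and every "edge" cell has degree 2 with both neighbours "node"
#' cells. Counting edge ends forces `n_edge = 3 * n_node / 2`, so `n_node`
#' must be even. The realisation is deterministic: a cubic (3-regular)
#' scaffold on the node cells — three parallel links for `n_node = 2`,
#' otherwise a circulant cycle plus the antipodal perfect matching — whose
#' every link is subdivided by one edge cell.
#'
#' @param n_node number of degree-3 node cells; even, at least 2.
#' @return A [group_graph()] whose first `n_node` cells are the node cells
#'   and remaining `3 * n_node / 2` cells are the edge cells.
#' @examples
#' g <- branching_graph(2)  # the minimal instance: K_{2,3}
#' g$degrees
#' @export
branching_graph <- function(n_node) {
  if (length(n_node) != 1 || n_node != round(n_node) || n_node < 2 ||
      n_node %% 2 != 0) {
    stop("invalid size: n_node must be an even integer >= 2 ",
         "(handshake requires n_edge = 3 * n_node / 2 to be an integer ",
         "realisable by a cubic scaffold)", call. = FALSE)
  }
  m <- as.integer(n_node)
  # cubic scaffold on node cells, as a list of (i, j) links (multigraph ok)
  if (m == 2) {
    links <- matrix(c(1, 2, 1, 2, 1, 2), ncol = 2, byrow = TRUE)
  } else {
    cyc <- cbind(seq_len(m), c(seq_len(m - 1) + 1L, 1L))
    mat <- cbind(seq_len(m / 2), seq_len(m / 2) + m / 2)
    links <- rbind(cyc, mat)
  }
  n_edge <- nrow(links)
  stopifnot(n_edge == 3 * m / 2)
  n <- m + n_edge
  A <- matrix(0, n, n)
  for (e in seq_len(n_edge)) {
    mid <- m + e
    A[links[e, 1], mid] <- A[mid, links[e, 1]] <- 1
    A[links[e, 2], mid] <- A[mid, links[e, 2]] <- 1
  }
  g <- group_graph(A)
  g$cell_type <- c(rep("node", m), rep("edge", n_edge))
  g
}

#' Well-mixed group structure
#'
#' The complete graph on `n > 2` cells: every cell shares with all
#' `n - 1` others, so each recipient gets a fraction `lambda / (n - 1)`
#' of a producer's shared good. This represents a group with no
#' topological constraint, under the same neighbour sharing rule as the
#' structured groups.
#'
#' @param n number of cells, greater than 2.
#' @return A [group_graph()].
#' @export
well_mixed_graph <- function(n) {
  if (length(n) != 1 || n != round(n) || n <= 2) {
    stop("invalid size: a well-mixed group needs n > 2", call. = FALSE)
  }
  n <- as.integer(n)
  A <- matrix(1, n, n)
  diag(A) <- 0
  group_graph(A)
}

#' Read and write edge-list files
#'
#' Edge lists are whitespace-separated integer pairs, one undirected edge
#' per line, with 0-based cell indices. Duplicate edges are collapsed and
#' symmetry is enforced on reading; the writer emits the sorted canonical
#' form (`i j` with `i < j`).
#'
#' @param path path to an edge-list text file.
#' @return `read_edge_list()` returns a [group_graph()];
#'   `write_edge_list()` returns `path` invisibly.
#' @export
read_edge_list <- function(path) {
  v <- scan(path, what = integer(), quiet = TRUE)
  if (length(v) == 0 || length(v) %% 2 != 0) {
    stop("format error: edge list must contain whitespace-separated ",
         "integer pairs", call. = FALSE)
  }
  e <- matrix(v, ncol = 2, byrow = TRUE)
  if (any(e < 0)) {
    stop("format error: cell indices are 0-based and non-negative",
         call. = FALSE)
  }
  if (any(e[, 1] == e[, 2])) {
    stop("format error: self-loop in edge list", call. = FALSE)
  }
  n <- max(e) + 1L
  A <- matrix(0, n, n)
  A[e + 1L] <- 1
  A[e[, 2:1] + 1L] <- 1
  group_graph(A)
}

#' @param graph a [group_graph()].
#' @rdname read_edge_list
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "group_graph"))
  idx <- which(upper.tri(graph$adjacency) & graph$adjacency == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  writeLines(sprintf("%d %d", idx[, 1] - 1L, idx[, 2] - 1L), path)
  invisible(path)
}

ROLE_LEVELS <- c("helper", "reproductive")

#' Role assignments
#'
#' A role assignment labels every cell either `"helper"` (high investment
#' in cooperation) or `"reproductive"` (low investment). Both roles must be
#' present. `alternating_roles()` gives the odd/even labelling natural on a
#' periodic filament; `roles_by_degree()` assigns `"helper"` to all cells
#' whose degree is below the group mean, which on a branching structure
#' makes the degree-2 edge cells helpers and the degree-3 node cells
#' reproductives.
#'
#' @param roles character vector over cells with entries `"helper"` or
#'   `"reproductive"`.
#' @return A validated character vector of class `role_assignment`.
#' @export
role_assignment <- function(roles) {
  roles <- as.character(roles)
  if (!all(roles %in% ROLE_LEVELS)) {
    stop("roles must be 'helper' or 'reproductive'", call. = FALSE)
  }
  if (!all(ROLE_LEVELS %in% roles)) {
    stop("need at least one helper and one reproductive", call. = FALSE)
  }
  structure(roles, class = "role_assignment")
}

#' @param graph a [group_graph()].
#' @rdname role_assignment
#' @export
alternating_roles <- function(graph) {
  n <- if (inherits(graph, "group_graph")) graph$n else as.integer(graph)
  if (n %% 2 != 0) {
    stop("alternating roles need an even number of cells", call. = FALSE)
  }
  role_assignment(rep(ROLE_LEVELS, n / 2))
}

#' @rdname role_assignment
#' @export
roles_by_degree <- function(graph) {
  stopifnot(inherits(graph, "group_graph"))
  role_assignment(ifelse(graph$degrees < mean(graph$degrees),
                         "helper", "reproductive"))
}

#' Class-structured summary of a role assignment
#'
#' Summarises a role partition of a group graph into two classes with the
#' neighbour-count table `k[c, c']`: the number of class-`c'` neighbours
#' that each class-`c` cell has. The summary is *equitable* when every cell
#' of a class has exactly the same neighbour-class counts; only then is the
#' mean-field two-variable group fitness `W(z_h, z_r)` an exact reduction
#' of the per-cell fitness. A non-equitable partition is a reported state
#' (with the offending cells listed), not an error.
#'
#' @param graph a [group_graph()].
#' @param roles a [role_assignment()] (or character vector) over all cells.
#' @return An object of class `class_structure` with fields `n_h`, `n_r`,
#'   `k` (2x2 matrix with dimnames `helper`/`reproductive`), `d` (per-class
#'   degree), `equitable`, `offenders`, `roles` and `graph`.
#' @examples
#' g <- filament_graph(6)
#' classify_partition(g, alternating_roles(g))
#' @export
classify_partition <- function(graph, roles) {
  stopifnot(inherits(graph, "group_graph"))
  roles <- role_assignment(roles)
  if (length(roles) != graph$n) {
    stop("roles must cover all cells", call. = FALSE)
  }
  is_h <- roles == "helper"
  A <- graph$adjacency
  to_h <- as.numeric(A %*% is_h)
  to_r <- as.numeric(A %*% (!is_h))
  k <- matrix(NA_real_, 2, 2, dimnames = list(ROLE_LEVELS, ROLE_LEVELS))
  offenders <- integer(0)
  for (cl in ROLE_LEVELS) {
    sel <- roles == cl
    kh <- unique(to_h[sel])
    kr <- unique(to_r[sel])
    k[cl, "helper"] <- to_h[sel][1]
    k[cl, "reproductive"] <- to_r[sel][1]
    if (length(kh) > 1 || length(kr) > 1) {
      off <- which(sel & (to_h != to_h[which(sel)[1]] |
                            to_r != to_r[which(sel)[1]]))
      offenders <- c(offenders, off)
    }
  }
  equitable <- length(offenders) == 0
  structure(
    list(
      n_h = sum(is_h), n_r = sum(!is_h),
      k = if (equitable) k else k * NA,
      d = if (equitable) {
        c(helper = sum(k["helper", ]), reproductive = sum(k["reproductive", ]))
      } else {
        c(helper = NA_real_, reproductive = NA_real_)
      },
      equitable = equitable,
      offenders = sort(unique(offenders)),
      roles = unclass(roles),
      graph = graph
    ),
    class = "class_structure"
  )
}

#' @export
print.class_structure <- function(x, ...) {
  cat(sprintf("class_structure: n_h = %d, n_r = %d, %s\n",
              x$n_h, x$n_r,
              if (x$equitable) "equitable" else
                sprintf("NOT equitable (offending cells: %s)",
                        paste(x$offenders - 1L, collapse = ", "))))
  if (x$equitable) {
    cat("neighbour-class counts k[c, c']:\n")
    print(x$k)
  }
  invisible(x)
}
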