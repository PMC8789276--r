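# graph fixtures built in code and finite-difference oracles shared by the
# test files

named_graph <- function(name) {
  ig <- igraph::make_graph(name)
  group_graph(as.matrix(igraph::as_adjacency_matrix(ig)))
}

random_connected_graph <- function(n, p_edge = 0.4) {
  repeat {
    A <- matrix(0, n, n)
    up <- which(upper.tri(A))
    A[up] <- as.numeric(stats::runif(length(up)) < p_edge)
    A <- A + t(A)
    ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    if (all(rowSums(A) >= 1) && igraph::is_connected(ig)) {
      return(group_graph(A))
    }
  }
}

# central finite differences of the two-class fitness surface
fd_class_gradient <- function(cs, lambda, model, z, h = 1e-5) {
  w <- function(zh, zr) class_group_fitness(cs, lambda, model, zh, zr)
  c(
    (w(z + h, z) - w(z - h, z)) / (2 * h),
    (w(z, z + h) - w(z, z - h)) / (2 * h)
  )
}

fd_class_hessian <- function(cs, lambda, model, z, h = 1e-4) {
  w <- function(zh, zr) class_group_fitness(cs, lambda, model, zh, zr)
  whh <- (w(z + h, z) - 2 * w(z, z) + w(z - h, z)) / h^2
  wrr <- (w(z, z + h) - 2 * w(z, z) + w(z, z - h)) / h^2
  whr <- (w(z + h, z + h) - w(z + h, z - h) -
            w(z - h, z + h) + w(z - h, z - h)) / (4 * h^2)
  matrix(c(whh, whr, whr, wrr), 2, 2)
}

# maximum group fitness over every helper/reproductive assignment (the
# best coordinated mutant for fixed role strategies)
max_partition_fitness <- function(graph, lambda, model, z_h, z_r) {
  n <- graph$n
  best <- -Inf
  for (mask in 0:(2^n - 1)) {
    is_h <- as.logical(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))))
    z <- ifelse(is_h, z_h, z_r)
    best <- max(best, group_fitness(graph, lambda, model, z))
  }
  best
}
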