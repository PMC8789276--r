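test_that("filament constructor builds cycles and paths with the right degrees", {
  g <- filament_graph(6)
  expect_equal(g$n, 6)
  expect_equal(g$degrees, rep(2, 6))

  open <- filament_graph(6, periodic = FALSE)
  expect_equal(open$degrees, c(1, 2, 2, 2, 2, 1))

  expect_error(filament_graph(3), "invalid size")
})

test_that("alternating roles on a cycle give the pure cross-class summary", {
  g <- filament_graph(6)
  cs <- classify_partition(g, alternating_roles(g))
  expect_true(cs$equitable)
  expect_equal(cs$n_h, 3)
  expect_equal(unname(cs$k["helper", "reproductive"]), 2)
  expect_equal(unname(cs$k["helper", "helper"]), 0)
  expect_equal(unname(cs$d), c(2, 2))
  expect_error(alternating_roles(filament_graph(5)), "even")
})

test_that("branching constructor satisfies the degree pattern and handshake", {
  b <- branching_graph(2)
  expect_equal(sort(b$degrees), c(2, 2, 2, 3, 3))
  # minimal instance is forced to be K_{2,3}
  expect_true(igraph::isomorphic(
    igraph::graph_from_adjacency_matrix(b$adjacency, mode = "undirected"),
    igraph::make_full_bipartite_graph(2, 3)
  ))
  cs <- classify_partition(b, roles_by_degree(b))
  expect_true(cs$equitable)
  expect_equal(c(cs$n_h, cs$n_r), c(3, 2))
  expect_equal(unname(cs$k["helper", "reproductive"]), 2)
  expect_equal(unname(cs$k["reproductive", "helper"]), 3)

  expect_error(branching_graph(3), "invalid size")

  for (m in c(2, 4, 6)) {
    g <- branching_graph(m)
    n_node <- sum(g$degrees == 3)
    n_edge <- sum(g$degrees == 2)
    expect_equal(n_node, m)
    expect_equal(2 * n_edge, 3 * n_node)  # handshake
    cs <- classify_partition(g, roles_by_degree(g))
    expect_true(cs$equitable)
    expect_equal(unname(cs$n_h * cs$k["helper", "reproductive"]),
                 unname(cs$n_r * cs$k["reproductive", "helper"]))
  }
})

test_that("well-mixed groups are complete graphs and any split is equitable", {
  g <- well_mixed_graph(5)
  expect_equal(g$degrees, rep(4, 5))
  cs <- classify_partition(
    g, role_assignment(c("helper", "helper", rep("reproductive", 3)))
  )
  expect_true(cs$equitable)
  expect_equal(unname(cs$k["helper", "helper"]), 1)
  expect_equal(unname(cs$k["helper", "reproductive"]), 3)
  expect_equal(unname(cs$k["reproductive", "reproductive"]), 2)
  expect_equal(unname(cs$k["reproductive", "helper"]), 2)
  expect_error(well_mixed_graph(2), "invalid size")
})

test_that("edge-list files parse, validate and round-trip", {
  f <- tempfile()
  writeLines(c("0 1", "1 2", "2 0"), f)
  tri <- read_edge_list(f)
  expect_equal(tri$degrees, rep(2, 3))

  writeLines(c("0 0", "0 1"), f)
  expect_error(read_edge_list(f), "self-loop")

  writeLines(c("0 1", "2 3", "3 4", "4 2"), f)  # two components
  expect_error(read_edge_list(f), "connected")

  # duplicate edges collapse
  writeLines(c("0 1", "1 0", "1 2", "2 0"), f)
  expect_equal(sum(read_edge_list(f)$adjacency) / 2, 3)

  # explicit C6 edge list is isomorphic to the periodic filament
  writeLines(c("0 2", "2 4", "4 1", "1 3", "3 5", "5 0"), f)
  g <- read_edge_list(f)
  expect_true(igraph::isomorphic(
    igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected"),
    igraph::graph_from_adjacency_matrix(filament_graph(6)$adjacency,
                                        mode = "undirected")
  ))

  # writer emits the canonical sorted form and reproduces the graph
  b <- branching_graph(4)
  out <- tempfile()
  write_edge_list(b, out)
  expect_equal(read_edge_list(out)$adjacency, b$adjacency)
  ends <- do.call(rbind, lapply(strsplit(readLines(out), " "), as.integer))
  expect_true(all(ends[, 1] < ends[, 2]))
  expect_false(is.unsorted(ends[, 1]))
})

test_that("graph validation rejects malformed adjacency", {
  A <- matrix(0, 3, 3); A[1, 2] <- 1  # asymmetric
  expect_error(group_graph(A), "symmetric")
  A <- diag(3)
  expect_error(group_graph(A), "self-loops")
  expect_error(group_graph(matrix(c(0, 1, 1, 0), 2, 2)), "n > 2")
})

test_that("non-equitable partitions are reported, not errors", {
  g <- filament_graph(6)
  blocks <- role_assignment(rep(c("helper", "reproductive"), each = 3))
  cs <- classify_partition(g, blocks)
  expect_false(cs$equitable)
  expect_true(length(cs$offenders) > 0)
  expect_error(class_group_fitness(cs, 0.5, power_tradeoff(1), 0.6, 0.4),
               "consistency error")
})

test_that("equitable summaries expand back to exact per-cell neighbour counts", {
  cases <- list(
    list(g = filament_graph(8), roles = alternating_roles(8)),
    list(g = branching_graph(4), roles = roles_by_degree(branching_graph(4))),
    list(g = well_mixed_graph(7),
         roles = role_assignment(rep(c("helper", "reproductive"), c(3, 4))))
  )
  for (case in cases) {
    cs <- classify_partition(case$g, case$roles)
    expect_true(cs$equitable)
    is_h <- cs$roles == "helper"
    to_h <- as.numeric(case$g$adjacency %*% is_h)
    to_r <- as.numeric(case$g$adjacency %*% (!is_h))
    for (i in seq_len(case$g$n)) {
      cl <- cs$roles[i]
      expect_equal(to_h[i], unname(cs$k[cl, "helper"]))
      expect_equal(to_r[i], unname(cs$k[cl, "reproductive"]))
    }
  }
})
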