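test_that("analytic derivatives match central finite differences across random draws", {
  set.seed(19)
  partitions <- list(
    classify_partition(filament_graph(6), alternating_roles(6)),
    classify_partition(filament_graph(10), alternating_roles(10)),
    classify_partition(branching_graph(2),
                       roles_by_degree(branching_graph(2))),
    classify_partition(branching_graph(4),
                       roles_by_degree(branching_graph(4))),
    classify_partition(well_mixed_graph(6),
                       role_assignment(rep(c("helper", "reproductive"), 3))),
    classify_partition(well_mixed_graph(9),
                       role_assignment(rep(c("helper", "reproductive"), c(4, 5))))
  )
  for (cs in partitions) {
    for (rep_i in 1:6) {
      lam <- runif(1, 0.05, 1)
      alpha <- runif(1, 0.4, 2)
      m <- power_tradeoff(alpha)
      z <- solve_uniform_ess(cs, lam, m)$z_star
      de <- analytic_derivatives(cs, lam, m, z)
      expect_equal(unname(de$gradient), fd_class_gradient(cs, lam, m, z),
                   tolerance = 1e-6)
      expect_equal(unname(de$hessian), fd_class_hessian(cs, lam, m, z),
                   tolerance = 1e-6)
      expect_equal(de$hessian[1, 2], de$hessian[2, 1])
    }
  }
})

test_that("filament Hessian entries have their closed forms for linear returns", {
  cs6 <- classify_partition(filament_graph(6), alternating_roles(6))
  m <- power_tradeoff(1)
  for (lam in c(0, 0.3, 0.6, 1)) {
    de <- analytic_derivatives(cs6, lam, m, 0.5)
    expect_equal(de$hessian[1, 1], -6 * (1 - lam))
    expect_equal(de$hessian[2, 2], -6 * (1 - lam))
    expect_equal(de$hessian[1, 2], -6 * lam)
  }
  # cross term vanishes without sharing
  expect_equal(analytic_derivatives(cs6, 0, m, 0.5)$hessian[1, 2], 0)
  # determinant flips sign across lambda = 1/2
  expect_lt(det(analytic_derivatives(cs6, 0.6, m, 0.5)$hessian), 0)
  expect_gt(det(analytic_derivatives(cs6, 0.4, m, 0.5)$hessian), 0)
})

test_that("invasion classification reproduces the canonical verdicts", {
  m1 <- power_tradeoff(1)
  cs6 <- classify_partition(filament_graph(6), alternating_roles(6))

  # filament above the one-half sharing threshold: saddle-driven invasion
  rp <- classify_invasion(cs6, 0.6, m1)
  expect_true(rp$invadable)
  expect_equal(rp$scenario, "reciprocal_specialisation")
  expect_true(rp$scenarios[["reciprocal_specialisation"]])
  expect_false(rp$scenarios[["between_individual_differences"]])

  # below the threshold: uniform cooperation stands
  rp <- classify_invasion(cs6, 0.4, m1)
  expect_false(rp$invadable)
  expect_equal(rp$scenario, "none")
  expect_equal(rp$benefit, 0)

  # branching with diminishing returns: first-order invasion whenever
  # anything is shared
  csb <- classify_partition(branching_graph(2),
                            roles_by_degree(branching_graph(2)))
  m08 <- power_tradeoff(0.8)
  for (lam in c(0.05, 0.3, 0.9)) {
    rp <- classify_invasion(csb, lam, m08, optimise = FALSE)
    expect_true(rp$invadable)
    expect_equal(rp$scenario, "between_individual_differences")
  }

  # accelerating returns flag for the filament requires
  # (alpha - 1) / alpha > 2 (1 - lambda); without sharing, the private
  # payoff (1 - z) z^alpha stays single-peaked for every alpha
  rp <- classify_invasion(cs6, 0.9, power_tradeoff(1.5), optimise = FALSE)
  expect_true(rp$scenarios[["accelerating_returns"]])
  expect_equal(rp$scenario, "accelerating_returns")
  for (alpha in c(0.5, 1, 1.5, 2)) {
    rp0 <- classify_invasion(cs6, 0, power_tradeoff(alpha), optimise = FALSE)
    expect_false(rp0$invadable)
  }
})

test_that("invadable flag agrees with a positive optimal benefit away from thresholds", {
  cs6 <- classify_partition(filament_graph(6), alternating_roles(6))
  m1 <- power_tradeoff(1)
  for (lam in c(0.1, 0.3, 0.42, 0.58, 0.7, 0.9, 1)) {
    rp <- classify_invasion(cs6, lam, m1)
    expect_equal(rp$invadable, rp$benefit > 1e-9,
                 info = sprintf("lambda = %g", lam))
  }
})

test_that("optimal specialisation finds the known optima on the filament", {
  cs6 <- classify_partition(filament_graph(6), alternating_roles(6))
  m1 <- power_tradeoff(1)

  opt <- optimal_specialisation(cs6, 1, m1)
  expect_equal(opt$z_h_opt, 1)
  expect_equal(opt$z_r_opt, 0)
  expect_equal(opt$benefit, 1)  # W doubles: 3 against 1.5

  expect_equal(optimal_specialisation(cs6, 0.4, m1)$benefit, 0)

  # cell-autonomous concave payoffs: nothing beats uniform cooperation
  csb <- classify_partition(branching_graph(2),
                            roles_by_degree(branching_graph(2)))
  for (alpha in c(0.5, 1)) {
    expect_equal(optimal_specialisation(csb, 0, power_tradeoff(alpha))$benefit, 0)
  }
})

test_that("the scenario-3 switch point on the filament is lambda = 1/2", {
  cs6 <- classify_partition(filament_graph(6), alternating_roles(6))
  m1 <- power_tradeoff(1)
  flag <- function(lam) {
    classify_invasion(cs6, lam, m1, optimise = FALSE)$scenarios[[
      "reciprocal_specialisation"]]
  }
  lo <- 0.3; hi <- 0.7
  expect_false(flag(lo)); expect_true(flag(hi))
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (flag(mid)) hi <- mid else lo <- mid
  }
  expect_equal((lo + hi) / 2, 0.5, tolerance = 1e-5)
})

test_that("the simplified linear condition agrees with the Hessian classification", {
  m1 <- power_tradeoff(1)
  cs6 <- classify_partition(filament_graph(6), alternating_roles(6))

  src <- simplified_reciprocal_condition(cs6, 0.6, m1)
  expect_true(src$applicable)
  expect_true(src$symmetric)
  expect_true(src$condition)
  expect_true(src$reduced)  # V_h^zh = 1 - lambda < lambda = V_h^zr

  src <- simplified_reciprocal_condition(cs6, 0.4, m1)
  expect_false(src$condition)
  expect_false(src$reduced)

  # boundary lambda = 1/2 resolves to no invasion under strict inequality
  src <- simplified_reciprocal_condition(cs6, 0.5, m1)
  expect_false(src$condition)

  # agreement with the scenario-3 flag across partitions and lambda
  partitions <- list(
    cs6,
    classify_partition(well_mixed_graph(6),
                       role_assignment(rep(c("helper", "reproductive"), 3))),
    classify_partition(well_mixed_graph(10),
                       role_assignment(rep(c("helper", "reproductive"), 5)))
  )
  # grid points chosen off the exact switch points, where the two strict
  # inequalities may legitimately disagree by rounding
  for (cs in partitions) {
    for (lam in c(seq(0.05, 0.95, by = 0.1), 1)) {
      src <- simplified_reciprocal_condition(cs, lam, m1)
      rp <- classify_invasion(cs, lam, m1, optimise = FALSE)
      expect_equal(src$condition,
                   rp$scenarios[["reciprocal_specialisation"]],
                   info = sprintf("lambda = %g", lam))
    }
  }

  # non-linear models are declared out of the simplified condition's scope
  expect_false(simplified_reciprocal_condition(cs6, 0.6,
                                               power_tradeoff(0.8))$applicable)
})

test_that("the full per-cell Hessian matches its closed form and the 2x2 reduction", {
  g6 <- filament_graph(6)
  m1 <- power_tradeoff(1)
  for (lam in c(0, 0.3, 0.6, 0.9)) {
    fh <- full_hessian(g6, lam, m1)
    expect_equal(fh$matrix,
                 -2 * (1 - lam) * diag(6) - lam * g6$adjacency)
    # leading-eigenvalue sign agrees with the saddle classification of the
    # mirror-symmetric alternating partition
    cs6 <- classify_partition(g6, alternating_roles(6))
    rp <- classify_invasion(cs6, lam, m1, optimise = FALSE)
    expect_equal(fh$unstable, rp$invadable)
  }
  expect_equal(full_hessian(g6, 0, m1)$matrix, -2 * diag(6))

  # well-mixed instability appears above lambda = (n - 1) / n
  k5 <- well_mixed_graph(5)
  expect_false(full_hessian(k5, 0.79, m1)$unstable)
  expect_true(full_hessian(k5, 0.81, m1)$unstable)

  # the instability direction on the cycle is the alternating labelling
  fh <- full_hessian(g6, 0.6, m1)
  bip <- fh$bipartition
  expect_true(all(bip[seq(1, 5, by = 2)] == bip[1]))
  expect_true(all(bip[seq(2, 6, by = 2)] == bip[2]))
  expect_false(bip[1] == bip[2])
})

test_that("full Hessian agrees with finite differences of per-cell fitness", {
  set.seed(5)
  g <- branching_graph(2)
  for (case in list(c(0.55, 0.8), c(0.9, 1.4))) {
    lam <- case[1]
    m <- power_tradeoff(case[2])
    fh <- full_hessian(g, lam, m)
    z0 <- rep(fh$z_star, g$n)
    h <- 1e-4
    num <- matrix(0, g$n, g$n)
    w <- function(z) group_fitness(g, lam, m, z)
    for (i in seq_len(g$n)) {
      for (j in seq_len(g$n)) {
        zpp <- z0; zpm <- z0; zmp <- z0; zmm <- z0
        if (i == j) {
          zp <- z0; zp[i] <- zp[i] + h
          zm <- z0; zm[i] <- zm[i] - h
          num[i, i] <- (w(zp) - 2 * w(z0) + w(zm)) / h^2
        } else {
          zpp[c(i, j)] <- zpp[c(i, j)] + h
          zpm[i] <- zpm[i] + h; zpm[j] <- zpm[j] - h
          zmp[i] <- zmp[i] - h; zmp[j] <- zmp[j] + h
          zmm[c(i, j)] <- zmm[c(i, j)] - h
          num[i, j] <- (w(zpp) - w(zpm) - w(zmp) + w(zmm)) / (4 * h^2)
        }
      }
    }
    expect_equal(fh$matrix, num, tolerance = 1e-5)
  }
})

test_that("non-equitable input falls back to the per-cell analysis", {
  g <- filament_graph(6)
  blocks <- role_assignment(rep(c("helper", "reproductive"), each = 3))
  cs <- classify_partition(g, blocks)
  m1 <- power_tradeoff(1)
  rp <- classify_invasion(cs, 0.6, m1)
  expect_false(rp$equitable)
  expect_true(rp$invadable)  # instability direction recovers the alternation
  expect_equal(rp$benefit, 0.2, tolerance = 1e-6)

  rp <- classify_invasion(cs, 0.4, m1)
  expect_false(rp$invadable)
})
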