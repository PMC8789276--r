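#' Analytic gradient and Hessian of two-class group fitness
#'
#' Assembles the five partial derivatives of
#' `W(z_h, z_r) = n_h F(z_h) V_h + n_r F(z_r) V_r`
#' at the uniform point `z_h = z_r = z_star`:
#'
#' * `W^zh = n_h F' V_h + n_h F V_h^zh + n_r F V_r^zh`
#' * `W^zr = n_r F' V_r + n_h F V_h^zr + n_r F V_r^zr`
#' * `W^zhzh = 2 n_h F' V_h^zh + n_h F'' V_h + n_h F V_h^zhzh + n_r F V_r^zhzh`
#' * `W^zrzr = 2 n_r F' V_r^zr + n_r F'' V_r + n_h F V_h^zrzr + n_r F V_r^zrzr`
#' * `W^zhzr = F' (n_h V_h^zr + n_r V_r^zh) + F (n_h V_h^zhzr + n_r V_r^zhzr)`
#'
#' where, under the neighbour sharing rule, the class viabilities are the
#' separable forms `V_h = c_hh H(z_h) + c_hr H(z_r)` (so the viability
#' cross-partials vanish), with sharing coefficients determined by the
#' equitable neighbour-count table.
#'
#' @param cs an equitable [classify_partition()] summary.
#' @param lambda shareability in `[0, 1]`.
#' @param model a [tradeoff_model()].
#' @param z_star uniform cooperation level at which to evaluate.
#' @return List with `gradient` (named length-2 vector) and `hessian`
#'   (symmetric 2x2 matrix), plus `z_star`.
#' @export
analytic_derivatives <- function(cs, lambda, model, z_star) {
  stopifnot(inherits(cs, "class_structure"))
  if (!cs$equitable) {
    stop("consistency error: partition is not equitable", call. = FALSE)
  }
  check_lambda(lambda)
  cc <- class_coefficients(cs, lambda)
  f <- model$f(z_star); f1 <- model$f1(z_star); f2 <- model$f2(z_star)
  h <- model$h(z_star); h1 <- model$h1(z_star); h2 <- model$h2(z_star)
  nh <- cs$n_h; nr <- cs$n_r
  V_h <- (cc$hh + cc$hr) * h
  V_r <- (cc$rh + cc$rr) * h
  Wzh <- nh * f1 * V_h + nh * f * cc$hh * h1 + nr * f * cc$rh * h1
  Wzr <- nr * f1 * V_r + nh * f * cc$hr * h1 + nr * f * cc$rr * h1
  Whh <- 2 * nh * f1 * cc$hh * h1 + nh * f2 * V_h +
    nh * f * cc$hh * h2 + nr * f * cc$rh * h2
  Wrr <- 2 * nr * f1 * cc$rr * h1 + nr * f2 * V_r +
    nh * f * cc$hr * h2 + nr * f * cc$rr * h2
  Whr <- f1 * (nh * cc$hr * h1 + nr * cc$rh * h1)
  H <- matrix(c(Whh, Whr, Whr, Wrr), 2, 2,
              dimnames = list(c("z_h", "z_r"), c("z_h", "z_r")))
  list(gradient = c(dW_dzh = unname(Wzh), dW_dzr = unname(Wzr)),
       hessian = H, z_star = z_star)
}

#' Classify invadability of uniform cooperation
#'
#' Evaluates the second-order expansion of mutant group fitness around the
#' uniform ES level `z*` on an equitable helper/reproductive partition and
#' flags the three routes by which a division-of-labour mutant can invade:
#'
#' * *accelerating returns* — a positive diagonal Hessian entry
#'   (`W^zhzh > 0` or `W^zrzr > 0`): a unilateral shift by one class is
#'   already favoured at second order;
#' * *between-individual differences* — a nonzero gradient
#'   (`W^zh != 0` or `W^zr != 0`): position in the group predisposes cells
#'   to one role, a first-order effect;
#' * *reciprocal specialisation* — both diagonals non-positive but a
#'   negative Hessian determinant: a saddle, where simultaneous opposite
#'   shifts by the two classes yield a synergistic group-fitness gain.
#'
#' Flags are reported independently; the `scenario` field gives the
#' first triggered route in the order above. Strict inequalities at the
#' thresholds resolve to "not invadable" (invasion requires a strictly
#' positive fitness difference); `tol` guards the comparisons.
#'
#' If the partition is not equitable the classification falls back to the
#' full per-cell Hessian ([full_hessian()]), taking roles from the sign
#' pattern of its leading eigenvector; if that induced partition is
#' equitable it is classified as usual, otherwise the verdict comes from
#' the per-cell gradient and leading eigenvalue directly.
#'
#' @param x an equitable [classify_partition()] summary, or a
#'   [group_graph()] (in which case `roles` must be given or is taken from
#'   the full-Hessian instability direction).
#' @inheritParams analytic_derivatives
#' @param roles optional [role_assignment()] when `x` is a graph.
#' @param tol comparison tolerance for the scenario flags.
#' @param optimise if `TRUE` (default), also locate the optimal
#'   division-of-labour strategy and its fitness benefit via
#'   [optimal_specialisation()].
#' @return An object of class `invasion_report`: `z_star`, `gradient`,
#'   `hessian`, logical `scenarios` (named flags), `invadable`, `scenario`
#'   (primary route or `"none"`), and when optimised `benefit`,
#'   `z_h_opt`, `z_r_opt`.
#' @examples
#' g <- filament_graph(6)
#' cs <- classify_partition(g, alternating_roles(g))
#' classify_invasion(cs, lambda = 0.6, power_tradeoff(1))
#' @export
classify_invasion <- function(x, lambda, model, roles = NULL, tol = 1e-9,
                              optimise = TRUE) {
  if (inherits(x, "group_graph")) {
    if (is.null(roles)) {
      fh <- full_hessian(x, lambda, model)
      roles <- fh$bipartition
    }
    x <- classify_partition(x, roles)
  }
  stopifnot(inherits(x, "class_structure"))
  cs <- x
  if (!cs$equitable) {
    return(classify_full(cs$graph, lambda, model, tol = tol,
                         optimise = optimise))
  }
  ess <- solve_uniform_ess(cs, lambda, model)
  de <- analytic_derivatives(cs, lambda, model, ess$z_star)
  g <- de$gradient
  Hm <- de$hessian
  s_diff <- max(abs(g)) > tol
  s_acc <- Hm[1, 1] > tol || Hm[2, 2] > tol
  s_rec <- Hm[1, 1] <= tol && Hm[2, 2] <= tol &&
    (Hm[1, 1] * Hm[2, 2] - Hm[1, 2]^2) < -tol
  scenarios <- c(
    accelerating_returns = s_acc,
    between_individual_differences = s_diff,
    reciprocal_specialisation = s_rec
  )
  out <- list(
    z_star = ess$z_star,
    W_star = ess$W_star,
    gradient = g,
    hessian = Hm,
    scenarios = scenarios,
    invadable = any(scenarios),
    scenario = if (any(scenarios)) names(scenarios)[which(scenarios)[1]] else "none",
    equitable = TRUE,
    n_h = cs$n_h, n_r = cs$n_r
  )
  if (optimise) {
    opt <- optimal_specialisation(cs, lambda, model)
    out$benefit <- opt$benefit
    out$z_h_opt <- opt$z_h_opt
    out$z_r_opt <- opt$z_r_opt
  }
  structure(out, class = "invasion_report")
}

# full-Hessian fallback for partitions with no equitable two-class summary
classify_full <- function(graph, lambda, model, tol = 1e-9, optimise = TRUE) {
  fh <- full_hessian(graph, lambda, model)
  s_diff <- max(abs(fh$gradient)) > tol
  s_curv <- fh$leading_eigenvalue > tol
  scenarios <- c(
    accelerating_returns = FALSE,
    between_individual_differences = s_diff,
    reciprocal_specialisation = s_curv
  )
  out <- list(
    z_star = fh$z_star,
    W_star = fh$W_star,
    gradient = fh$gradient,
    hessian = fh$matrix,
    scenarios = scenarios,
    invadable = any(scenarios),
    scenario = if (any(scenarios)) names(scenarios)[which(scenarios)[1]] else "none",
    equitable = FALSE,
    bipartition = fh$bipartition
  )
  if (optimise) {
    cs2 <- classify_partition(graph, fh$bipartition)
    if (cs2$equitable) {
      opt <- optimal_specialisation(cs2, lambda, model)
      out$benefit <- opt$benefit
      out$z_h_opt <- opt$z_h_opt
      out$z_r_opt <- opt$z_r_opt
    } else {
      out$benefit <- NA_real_
    }
  }
  structure(out, class = "invasion_report")
}

#' @export
print.invasion_report <- function(x, ...) {
  cat(sprintf("invasion_report: z* = %.6g, %s\n", x$z_star,
              if (x$invadable) sprintf("INVADABLE (%s)", x$scenario)
              else "not invadable"))
  cat(sprintf("  gradient: (%.6g, %.6g)\n", x$gradient[1], x$gradient[2]))
  if (is.matrix(x$hessian) && all(dim(x$hessian) == c(2, 2))) {
    cat(sprintf("  hessian:  [%.6g, %.6g; %.6g, %.6g]  det = %.6g\n",
                x$hessian[1, 1], x$hessian[1, 2], x$hessian[2, 1],
                x$hessian[2, 2], det(x$hessian)))
  }
  flg <- names(x$scenarios)[x$scenarios]
  cat("  scenarios:", if (length(flg)) paste(flg, collapse = ", ") else "none", "\n")
  if (!is.null(x$benefit) && !is.na(x$benefit)) {
    cat(sprintf("  benefit:  %.6g at (z_h, z_r) = (%.4g, %.4g)\n",
                x$benefit, x$z_h_opt, x$z_r_opt))
  }
  invisible(x)
}

#' Simplified reciprocal specialisation condition for linear models
#'
#' For models in which fecundity and the class viabilities are linear (all
#' second derivatives zero) the saddle condition reduces to
#' `4 n_h V_h^zh n_r V_r^zr < (n_h V_h^zr + n_r V_r^zh)^2`, and when the
#' viabilities are symmetrical (`n_h V_h(a, b) = n_r V_r(b, a)`) further to
#' `V_h^zh < V_h^zr`: reproductives' viability must increase faster with
#' helper cooperation than with their own. Both forms agree with the
#' Hessian-determinant classification, which the test suite asserts.
#'
#' @inheritParams analytic_derivatives
#' @return A list with `applicable` (FALSE for non-linear models, in which
#'   case the remaining fields are `NA`), `condition` (the general linear
#'   form), `symmetric` (whether the viability symmetry holds) and
#'   `reduced` (the reduced form, `NA` unless symmetric).
#' @export
simplified_reciprocal_condition <- function(cs, lambda, model) {
  stopifnot(inherits(cs, "class_structure"))
  zt <- seq(0.05, 0.95, by = 0.09)
  linear <- max(abs(model$f2(zt))) < 1e-8 && max(abs(model$h2(zt))) < 1e-8
  if (!linear) {
    return(list(applicable = FALSE, condition = NA, symmetric = NA,
                reduced = NA))
  }
  cc <- class_coefficients(cs, lambda)
  h1 <- model$h1(0.5)  # constant for linear H
  nh <- cs$n_h; nr <- cs$n_r
  Vh_zh <- cc$hh * h1; Vh_zr <- cc$hr * h1
  Vr_zh <- cc$rh * h1; Vr_zr <- cc$rr * h1
  cond <- 4 * nh * Vh_zh * nr * Vr_zr < (nh * Vh_zr + nr * Vr_zh)^2
  sym <- symmetry_check(cs, lambda, model)
  list(applicable = TRUE, condition = cond, symmetric = sym,
       reduced = if (sym) Vh_zh < Vh_zr else NA)
}

#' Full per-cell Hessian of group fitness at the uniform ESS
#'
#' Builds the `n x n` second-derivative matrix of
#' `W(z_1, ..., z_n) = sum_i F(z_i) V_i` at the uniform point
#' `z_i = z*`, the n-variable generalisation of the two-class expansion.
#' Under the neighbour sharing rule the entries are, at the uniform point,
#' `d2W/dz_k2 = F'' H s_k + 2 (1 - lambda) F' H' + F H''` with
#' `s_k = (1 - lambda) + lambda * sum_{j ~ k} 1 / d_j`, and
#' `d2W/dz_k dz_l = lambda F' H' (1 / d_k + 1 / d_l)` for neighbours
#' `k ~ l` (zero otherwise). For the linear parametric model on a
#' d-regular graph this is `-2 (1 - lambda) I - (2 lambda / d) A`.
#'
#' A positive leading eigenvalue means the uniform point is unstable to
#' some joint per-cell perturbation; the sign pattern of the leading
#' eigenvector proposes the helper/reproductive partition that realises
#' the instability.
#'
#' @param graph a [group_graph()].
#' @inheritParams analytic_derivatives
#' @return An object of class `full_hessian_report`: `matrix`,
#'   `leading_eigenvalue`, `leading_eigenvector`, `unstable`, proposed
#'   `bipartition`, the per-cell `gradient` at the uniform point, `z_star`
#'   and `W_star`.
#' @export
full_hessian <- function(graph, lambda, model) {
  stopifnot(inherits(graph, "group_graph"))
  check_lambda(lambda)
  ess <- solve_uniform_ess(graph, lambda, model)
  z <- ess$z_star
  f <- model$f(z); f1 <- model$f1(z); f2 <- model$f2(z)
  h <- model$h(z); h1 <- model$h1(z); h2 <- model$h2(z)
  d <- graph$degrees
  A <- graph$adjacency
  s <- (1 - lambda) + lambda * as.numeric(A %*% (1 / d))
  diag_terms <- f2 * h * s + 2 * (1 - lambda) * f1 * h1 + f * h2
  M <- lambda * f1 * h1 * (outer(1 / d, 1 / d, "+")) * A
  diag(M) <- diag_terms
  # per-cell first derivative at the uniform point
  grad <- f1 * h * s + f * h1
  eig <- eigen(M, symmetric = TRUE)
  v <- eig$vectors[, 1]
  if (sum(v) < 0) v <- -v
  # helper/reproductive proposal from the instability direction: sign
  # pattern when both signs occur, otherwise a balanced rank split
  bip <- if (any(v > 1e-12) && any(v < -1e-12)) {
    ifelse(v > 0, "helper", "reproductive")
  } else {
    ifelse(rank(v, ties.method = "first") > length(v) / 2,
           "helper", "reproductive")
  }
  structure(
    list(
      matrix = M,
      leading_eigenvalue = eig$values[1],
      leading_eigenvector = v,
      unstable = eig$values[1] > 1e-10,
      bipartition = role_assignment(bip),
      gradient = grad,
      z_star = z,
      W_star = ess$W_star
    ),
    class = "full_hessian_report"
  )
}

#' @export
print.full_hessian_report <- function(x, ...) {
  cat(sprintf(
    "full_hessian_report: n = %d, leading eigenvalue %.6g (%s) at z* = %.6g\n",
    nrow(x$matrix), x$leading_eigenvalue,
    if (x$unstable) "unstable" else "stable", x$z_star))
  invisible(x)
}

#' Optimal division-of-labour strategy and its fitness benefit
#'
#' Maximises the two-class group fitness `W(z_h, z_r)` over the admissible
#' square with `z_h >= z_r` (without loss of generality: helpers are the
#' more cooperative class) by a coarse grid followed by local refinement,
#' and reports the relative fitness benefit of the best division of labour
#' over uniform cooperation, `W_max / W(z*, z*) - 1`, floored at zero.
#'
#' @inheritParams analytic_derivatives
#' @param grid_n number of grid points per axis for the coarse search.
#' @param refine if `TRUE` (default) polish the grid optimum with
#'   box-constrained BFGS.
#' @return List with `z_h_opt`, `z_r_opt`, `W_max`, `W_star` and `benefit`.
#' @examples
#' g <- filament_graph(6)
#' cs <- classify_partition(g, alternating_roles(g))
#' optimal_specialisation(cs, 1, power_tradeoff(1))  # full specialisation
#' @export
optimal_specialisation <- function(cs, lambda, model, grid_n = 201,
                                   refine = TRUE) {
  stopifnot(inherits(cs, "class_structure"))
  zs <- seq(0, 1, length.out = grid_n)
  zz <- expand.grid(z_h = zs, z_r = zs)
  keep <- zz$z_h >= zz$z_r
  W <- rep(-Inf, nrow(zz))
  W[keep] <- class_group_fitness(cs, lambda, model, zz$z_h[keep], zz$z_r[keep])
  i <- which.max(W)
  best <- c(zz$z_h[i], zz$z_r[i])
  W_max <- W[i]
  if (refine) {
    obj <- function(p) {
      if (p[1] < p[2]) return(Inf)
      -class_group_fitness(cs, lambda, model, p[1], p[2])
    }
    o <- try(stats::optim(best, obj, method = "L-BFGS-B",
                          lower = c(0, 0), upper = c(1, 1)), silent = TRUE)
    if (!inherits(o, "try-error") && is.finite(o$value) && -o$value > W_max) {
      best <- o$par
      W_max <- -o$value
    }
  }
  ess <- solve_uniform_ess(cs, lambda, model)
  list(z_h_opt = best[1], z_r_opt = best[2], W_max = W_max,
       W_star = ess$W_star,
       benefit = max(0, W_max / ess$W_star - 1))
}
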