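#' Uniform evolutionarily stable cooperation level
#'
#' Solves for the resident cooperation level `z*` at which no *uniform*
#' change in cooperation by all cells is favoured, i.e. the root of
#' `d/dz W(z, ..., z) = 0`. Because the sharing rule conserves the public
#' good, the uniform-profile fitness is `W(z, ..., z) = n F(z) H(z)` on
#' every topology and for every shareability, so `z*` depends only on the
#' tradeoff model; for the parametric family `F = 1 - z`, `H = z^alpha`
#' it is `z* = alpha / (1 + alpha)`.
#'
#' The root is found by sign-change bracketing on `[1e-9, 1 - 1e-9]`
#' followed by bisection ([stats::uniroot()]). If the derivative does not
#' change sign in the bracket, the better boundary of the admissible range
#' is reported with `boundary_flag = TRUE` rather than an error. Multiple
#' sign changes (which do not arise for the in-scope family) raise a
#' warning and return the smallest root.
#'
#' @param group a [group_graph()] or [classify_partition()] summary;
#'   used for the group size (the location of `z*` is structure-free, which
#'   the test suite asserts).
#' @param lambda shareability in `[0, 1]`.
#' @param model a [tradeoff_model()].
#' @param tol solver tolerance on `z*`.
#' @return An object of class `uniform_ess` with fields `z_star`,
#'   `derivative_residual`, `boundary_flag` and `W_star` (uniform group
#'   fitness at `z*`).
#' @examples
#' solve_uniform_ess(filament_graph(6), 0.5, power_tradeoff(1))$z_star  # 0.5
#' @export
solve_uniform_ess <- function(group, lambda, model, tol = 1e-10) {
  stopifnot(inherits(model, "tradeoff_model"))
  check_lambda(lambda)
  n <- if (inherits(group, "class_structure")) {
    cs_n(group)
  } else if (inherits(group, "group_graph")) {
    group$n
  } else {
    stop("group must be a group_graph or class_structure", call. = FALSE)
  }
  # d/dz [n F(z) H(z)] up to the positive factor n
  dW <- function(z) model$f1(z) * model$h(z) + model$f(z) * model$h1(z)
  lo <- 1e-9
  hi <- 1 - 1e-9
  zg <- seq(lo, hi, length.out = 1001)
  gv <- dW(zg)
  # a grid point may land exactly on the root (e.g. z = 1/2 for alpha = 1)
  exact <- which(gv == 0)
  if (length(exact) > 0) {
    z_star <- zg[exact[1]]
    if (length(exact) > 1) {
      warning("multiple roots of the uniform selection gradient; ",
              "returning the smallest")
    }
    return(structure(
      list(z_star = z_star, derivative_residual = 0, boundary_flag = FALSE,
           W_star = n * model$f(z_star) * model$h(z_star)),
      class = "uniform_ess"
    ))
  }
  sgn <- sign(gv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(flips) == 0) {
    z_star <- if (model$f(hi) * model$h(hi) > model$f(lo) * model$h(lo)) 1 else 0
    res <- list(z_star = z_star, derivative_residual = NA_real_,
                boundary_flag = TRUE,
                W_star = n * model$f(z_star) * model$h(z_star))
    return(structure(res, class = "uniform_ess"))
  }
  if (length(flips) > 1) {
    warning("multiple sign changes in the uniform selection gradient; ",
            "returning the smallest root")
  }
  i <- flips[1]
  root <- stats::uniroot(dW, c(zg[i], zg[i + 1]), tol = tol)
  structure(
    list(z_star = root$root, derivative_residual = dW(root$root),
         boundary_flag = FALSE,
         W_star = n * model$f(root$root) * model$h(root$root)),
    class = "uniform_ess"
  )
}

cs_n <- function(cs) cs$n_h + cs$n_r

#' @export
print.uniform_ess <- function(x, ...) {
  cat(sprintf("uniform_ess: z* = %.10g%s (W* = %.6g)\n", x$z_star,
              if (x$boundary_flag) " [boundary]" else "", x$W_star))
  invisible(x)
}

#' Directional selection balance at the uniform ESS
#'
#' Returns the pair of class-directional derivatives
#' `(dW/dz_h, dW/dz_r)` evaluated at `(z*, z*)`. At the uniform ES level
#' any increase in fitness from increased cooperation by one class is
#' balanced by a commensurate decrease from the same increase by the other
#' class, so the two derivatives always sum to zero. Both are individually
#' zero exactly when the partition carries no between-individual
#' differences (the uniform point is then a true critical point).
#'
#' @param cs an equitable [classify_partition()] summary.
#' @inheritParams solve_uniform_ess
#' @param ess optionally, a precomputed [solve_uniform_ess()] result.
#' @return Named numeric vector `c(dW_dzh, dW_dzr)`.
#' @export
gradient_balance <- function(cs, lambda, model, ess = NULL) {
  if (is.null(ess)) ess <- solve_uniform_ess(cs, lambda, model)
  d <- analytic_derivatives(cs, lambda, model, ess$z_star)
  d$gradient
}
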