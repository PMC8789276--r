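#' Viability-fecundity tradeoff models
#'
#' A tradeoff model couples a fecundity function `F(z)` (decreasing in own
#' cooperation `z`) with a public-good production function `H(z)`
#' (increasing in `z`), both on the admissible cooperation range `[0, 1]`.
#' Individual fitness is the product of fecundity and viability, where
#' viability is the total public good a cell absorbs.
#'
#' `power_tradeoff(alpha)` is the parametric family `F(z) = 1 - z`,
#' `H(z) = z^alpha`: a linear return from fecundity specialisation with a
#' return exponent `alpha` controlling the shape of the cooperative return
#' (`alpha > 1` accelerating, `alpha < 1` diminishing). Full specialisation
#' `z = 1` is admissible as a limit, with `F(1) = 0` treated exactly (zero
#' fitness contribution).
#'
#' `tradeoff_model()` accepts arbitrary user-supplied functions; derivative
#' accessors default to central finite differences with step `1e-5` when
#' not given analytically.
#'
#' @param fecundity,good functions of the cooperation level `z`
#'   (vectorised), with `fecundity` decreasing and `good` increasing on the
#'   interior of `[0, 1]`, `good(z) >= 0`.
#' @param d_fecundity,d_good,d2_fecundity,d2_good optional first and second
#'   derivative functions; finite differences are substituted when `NULL`.
#' @param alpha return exponent, recorded when the model is the parametric
#'   power family (`NA` otherwise).
#' @return An object of class `tradeoff_model` with function fields
#'   `f, h, f1, h1, f2, h2`, the exponent `alpha`, and `parametric` flag.
#' @examples
#' m <- power_tradeoff(0.8)
#' m$h(0.5)
#' @export
tradeoff_model <- function(fecundity, good,
                           d_fecundity = NULL, d_good = NULL,
                           d2_fecundity = NULL, d2_good = NULL,
                           alpha = NA_real_) {
  stopifnot(is.function(fecundity), is.function(good))
  fd1 <- function(fn) function(z) (fn(z + 1e-5) - fn(z - 1e-5)) / 2e-5
  fd2 <- function(fn) function(z) (fn(z + 1e-5) - 2 * fn(z) + fn(z - 1e-5)) / 1e-10
  m <- structure(
    list(
      f = fecundity, h = good,
      f1 = if (is.null(d_fecundity)) fd1(fecundity) else d_fecundity,
      h1 = if (is.null(d_good)) fd1(good) else d_good,
      f2 = if (is.null(d2_fecundity)) fd2(fecundity) else d2_fecundity,
      h2 = if (is.null(d2_good)) fd2(good) else d2_good,
      alpha = alpha,
      parametric = !is.na(alpha)
    ),
    class = "tradeoff_model"
  )
  zt <- seq(0.05, 0.95, by = 0.15)
  if (any(m$h(zt) < 0)) stop("good production H(z) must be >= 0", call. = FALSE)
  if (any(m$f1(zt) >= 0)) {
    stop("fecundity must be strictly decreasing on the interior ",
         "(viability-fecundity tradeoff)", call. = FALSE)
  }
  if (any(m$h1(zt) <= 0)) {
    stop("good production must be strictly increasing on the interior",
         call. = FALSE)
  }
  m
}

#' @rdname tradeoff_model
#' @export
power_tradeoff <- function(alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0)
  tradeoff_model(
    fecundity = function(z) 1 - z,
    good = function(z) z^alpha,
    d_fecundity = function(z) rep(-1, length(z)),
    d_good = function(z) alpha * z^(alpha - 1),
    d2_fecundity = function(z) rep(0, length(z)),
    d2_good = function(z) {
      co <- alpha * (alpha - 1)
      if (co == 0) rep(0, length(z)) else co * z^(alpha - 2)
    },
    alpha = alpha
  )
}

#' @export
print.tradeoff_model <- function(x, ...) {
  if (x$parametric) {
    cat(sprintf("tradeoff_model: F(z) = 1 - z, H(z) = z^%g\n", x$alpha))
  } else {
    cat("tradeoff_model: user-supplied F and H\n")
  }
  invisible(x)
}

check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || lambda > 1) {
    stop("shareability lambda must lie in [0, 1]", call. = FALSE)
  }
  lambda
}

check_z <- function(z) {
  if (anyNA(z) || any(z < 0) || any(z > 1)) {
    stop("cooperation levels must lie in the admissible range [0, 1]",
         call. = FALSE)
  }
  z
}

#' Per-cell viabilities under neighbour sharing
#'
#' A cell investing `z_i` produces `H(z_i)` of public good, keeps the
#' fraction `1 - lambda`, and shares the fraction `lambda` equally among
#' its `d_i` direct neighbours. Viability is the total good absorbed:
#' `V_i = (1 - lambda) H(z_i) + lambda * sum_{j ~ i} H(z_j) / d_j`.
#' The sharing rule redistributes but never creates or destroys good, so
#' `sum_i V_i = sum_i H(z_i)` for every graph and every lambda.
#'
#' @param graph a [group_graph()].
#' @param lambda shareability in `[0, 1]` (`lambda = 0`, no sharing, is
#'   permitted for degenerate checks).
#' @param model a [tradeoff_model()].
#' @param z per-cell cooperation levels in `[0, 1]`, length `n`.
#' @return Numeric vector of per-cell viabilities.
#' @export
viability_profile <- function(graph, lambda, model, z) {
  stopifnot(inherits(graph, "group_graph"), inherits(model, "tradeoff_model"))
  check_lambda(lambda)
  check_z(z)
  if (length(z) != graph$n) stop("profile must have length n", call. = FALSE)
  hz <- model$h(z)
  (1 - lambda) * hz +
    lambda * as.numeric(graph$adjacency %*% (hz / graph$degrees))
}

#' Group fitness
#'
#' Group fitness is the sum of individual fitness, each the product of own
#' fecundity and viability: `W = sum_i F(z_i) V_i`. Because sharing
#' conserves the public good, a uniform profile has
#' `W(z, ..., z) = n F(z) H(z)` for every topology and shareability.
#'
#' @inheritParams viability_profile
#' @return Group fitness, a scalar.
#' @examples
#' g <- filament_graph(6)
#' group_fitness(g, 0.5, power_tradeoff(1), rep(0.5, 6))  # = 6 * 0.5 * 0.5
#' @export
group_fitness <- function(graph, lambda, model, z) {
  sum(model$f(check_z(z)) * viability_profile(graph, lambda, model, z))
}

# sharing coefficients of the two-class viabilities:
#   V_h = c_hh H(z_h) + c_hr H(z_r),  V_r = c_rh H(z_h) + c_rr H(z_r)
class_coefficients <- function(cs, lambda) {
  k <- cs$k
  d <- cs$d
  list(
    hh = unname((1 - lambda) + lambda * k["helper", "helper"] / d["helper"]),
    hr = unname(lambda * k["helper", "reproductive"] / d["reproductive"]),
    rh = unname(lambda * k["reproductive", "helper"] / d["helper"]),
    rr = unname((1 - lambda) +
                  lambda * k["reproductive", "reproductive"] / d["reproductive"])
  )
}

#' Two-class viabilities and group fitness on an equitable partition
#'
#' On an equitable helper/reproductive partition every cell of a class has
#' identical neighbour-class counts, so the per-cell fitness collapses
#' exactly to the two-variable form
#' `W(z_h, z_r) = n_h F(z_h) V_h + n_r F(z_r) V_r` with
#' `V_h = (1 - lambda) H(z_h) + lambda (k_hh H(z_h) / d_h + k_hr H(z_r) / d_r)`
#' and the analogous `V_r`. Both functions are vectorised over
#' `(z_h, z_r)` pairs.
#'
#' @param cs an equitable [classify_partition()] summary.
#' @param lambda shareability in `[0, 1]`.
#' @param model a [tradeoff_model()].
#' @param z_h,z_r cooperation levels of helpers and reproductives.
#' @return `class_viabilities()` returns a list with vectors `V_h`, `V_r`;
#'   `class_group_fitness()` returns the group fitness vector.
#' @export
class_viabilities <- function(cs, lambda, model, z_h, z_r) {
  stopifnot(inherits(cs, "class_structure"))
  if (!cs$equitable) {
    stop("consistency error: partition is not equitable; the two-class ",
         "reduction is undefined", call. = FALSE)
  }
  check_lambda(lambda)
  cc <- class_coefficients(cs, lambda)
  hh <- model$h(check_z(z_h))
  hr <- model$h(check_z(z_r))
  list(V_h = cc$hh * hh + cc$hr * hr, V_r = cc$rh * hh + cc$rr * hr)
}

#' @rdname class_viabilities
#' @export
class_group_fitness <- function(cs, lambda, model, z_h, z_r) {
  v <- class_viabilities(cs, lambda, model, z_h, z_r)
  as.numeric(cs$n_h * model$f(z_h) * v$V_h + cs$n_r * model$f(z_r) * v$V_r)
}

#' Viability symmetry check
#'
#' Tests whether the two class viabilities are symmetrical in the sense
#' `n_h V_h(z_h, z_r) = n_r V_r(z_r, z_h)` identically (checked on a grid
#' of `(z_h, z_r)` pairs). When this holds, `W(z_h, z_r) = W(z_r, z_h)`
#' and the uniform ES point is a true critical point of the two-variable
#' fitness, not merely a constrained optimum.
#'
#' @inheritParams class_viabilities
#' @param grid vector of test levels in `[0, 1]`.
#' @param tol numeric tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
symmetry_check <- function(cs, lambda, model, grid = seq(0, 1, by = 0.1),
                           tol = 1e-10) {
  zz <- expand.grid(z_h = grid, z_r = grid)
  a <- class_viabilities(cs, lambda, model, zz$z_h, zz$z_r)
  b <- class_viabilities(cs, lambda, model, zz$z_r, zz$z_h)
  max(abs(cs$n_h * a$V_h - cs$n_r * b$V_r)) < tol
}
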