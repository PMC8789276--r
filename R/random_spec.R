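#' Expected group fitness under random (uncoordinated) role assignment
#'
#' A division-of-labour mutant without any between-cell coordination makes
#' each cell adopt the helper role (cooperation `z_h`) independently with
#' probability `p` and the reproductive role (`z_r`) otherwise. Because a
#' cell's fecundity is independent of its neighbours' identities and the
#' sharing rule conserves the public good (`sum_i sum_{j ~ i} 1/d_j = n`),
#' the expected group fitness has the closed form
#' `n * ((1 - lambda) E[F H] + lambda E[F] E[H])`
#' with expectations over the two-point role distribution — it contains no
#' graph term at all, so randomising roles erases every topological
#' benefit.
#'
#' Three evaluation methods are provided: `closed_form` (the formula),
#' `enumerate` (exact sum of `W` over all `2^n` assignments weighted by
#' the Bernoulli probabilities; `n <= 20`), and `monte_carlo` (seeded
#' averaging over sampled assignments, returned with a standard error in
#' attribute `"se"`). With `fixed_count = TRUE` the enumeration is instead
#' over assignments with exactly `n_h` helpers (a sensitivity variant; the
#' closed form does not apply because roles are then negatively
#' correlated).
#'
#' @param graph a [group_graph()].
#' @param lambda shareability in `[0, 1]`.
#' @param model a [tradeoff_model()].
#' @param p helper probability in `[0, 1]`.
#' @param z_h,z_r helper and reproductive cooperation levels.
#' @param method one of `"closed_form"`, `"enumerate"`, `"monte_carlo"`.
#' @param replicates Monte Carlo replicate count.
#' @param seed RNG seed, mandatory for `monte_carlo`; the global RNG state
#'   is restored on exit.
#' @param fixed_count if `TRUE`, condition on exactly `n_h` helpers
#'   (enumeration only).
#' @param n_h helper count for `fixed_count`.
#' @return Expected group fitness (scalar); for `monte_carlo` with a
#'   standard-error attribute `"se"`.
#' @examples
#' g <- filament_graph(6)
#' expected_fitness_random(g, 0.7, power_tradeoff(1), p = 0.5,
#'                         z_h = 0.8, z_r = 0.2)
#' @export
expected_fitness_random <- function(graph, lambda, model, p, z_h, z_r,
                                    method = c("closed_form", "enumerate",
                                               "monte_carlo"),
                                    replicates = 1e5, seed = NULL,
                                    fixed_count = FALSE, n_h = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(graph, "group_graph"), inherits(model, "tradeoff_model"))
  check_lambda(lambda)
  check_z(c(z_h, z_r))
  if (!is.numeric(p) || length(p) != 1 || p < 0 || p > 1) {
    stop("helper probability p must lie in [0, 1]", call. = FALSE)
  }
  n <- graph$n
  if (fixed_count) {
    if (method != "enumerate") {
      stop("size error: the fixed-count variant is evaluated by enumeration",
           call. = FALSE)
    }
    if (is.null(n_h) || n_h < 1 || n_h > n - 1) {
      stop("fixed_count requires n_h in 1..(n-1)", call. = FALSE)
    }
  }
  switch(method,
    closed_form = {
      fh <- model$f(z_h); fr <- model$f(z_r)
      hh <- model$h(z_h); hr <- model$h(z_r)
      EFH <- p * fh * hh + (1 - p) * fr * hr
      EF <- p * fh + (1 - p) * fr
      EH <- p * hh + (1 - p) * hr
      n * ((1 - lambda) * EFH + lambda * EF * EH)
    },
    enumerate = {
      if (n > 20) {
        stop("size error: enumeration is restricted to n <= 20", call. = FALSE)
      }
      if (fixed_count) {
        sets <- utils::combn(n, n_h)
        total <- 0
        for (j in seq_len(ncol(sets))) {
          z <- rep(z_r, n)
          z[sets[, j]] <- z_h
          total <- total + group_fitness(graph, lambda, model, z)
        }
        total / ncol(sets)
      } else {
        total <- 0
        for (mask in 0:(2^n - 1)) {
          is_h <- as.logical(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))))
          k <- sum(is_h)
          w <- p^k * (1 - p)^(n - k)
          if (w == 0) next
          z <- ifelse(is_h, z_h, z_r)
          total <- total + w * group_fitness(graph, lambda, model, z)
        }
        total
      }
    },
    monte_carlo = {
      if (is.null(seed)) {
        stop("monte_carlo requires an explicit seed", call. = FALSE)
      }
      has_seed <- exists(".Random.seed", envir = globalenv())
      if (has_seed) old <- get(".Random.seed", envir = globalenv())
      on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
      R <- matrix(stats::runif(replicates * n) < p, replicates, n)
      HZ <- ifelse(R, model$h(z_h), model$h(z_r))
      FZ <- ifelse(R, model$f(z_h), model$f(z_r))
      V <- (1 - lambda) * HZ +
        lambda * (sweep(HZ, 2, graph$degrees, "/") %*% graph$adjacency)
      Ws <- rowSums(FZ * V)
      out <- mean(Ws)
      attr(out, "se") <- stats::sd(Ws) / sqrt(replicates)
      out
    }
  )
}

#' Critical return exponent under random specialisation
#'
#' Finds, by bisection, the smallest return exponent `alpha` at which some
#' uncoordinated division-of-labour strategy — a helper probability and
#' role strategies `(p, z_h, z_r)` searched on a grid — achieves a higher
#' expected group fitness (closed form) than the uniform ES strategy. For
#' `alpha <= 1` no such strategy exists for any shareability; the
#' threshold decreases towards 1 as `lambda` grows and equals 1 exactly at
#' full sharing (`lambda = 1`), where the strategy
#' `(p = 1/2, z_h = 1, z_r = 0)` keeps expected fitness `n/4` for every
#' exponent while the uniform-ES fitness falls. The grid is only used to
#' witness existence; the closed form is smooth in all arguments.
#'
#' @inheritParams expected_fitness_random
#' @param tol bisection tolerance on `alpha`.
#' @param p_grid helper-probability search grid.
#' @param z_points number of points of the cooperation search grid on
#'   `[0, 1]` for each of `z_h`, `z_r`.
#' @param alpha_range bracketing interval for the bisection.
#' @param indicator_tol strictly-positive margin required to count as
#'   invasion.
#' @return The critical exponent (scalar). `NA` with a warning if the
#'   indicator does not change over `alpha_range`.
#' @export
critical_alpha_random <- function(graph, lambda, tol = 1e-3,
                                  p_grid = seq(0.1, 0.9, by = 0.1),
                                  z_points = 101,
                                  alpha_range = c(0.5, 2),
                                  indicator_tol = 1e-9) {
  stopifnot(inherits(graph, "group_graph"))
  check_lambda(lambda)
  n <- graph$n
  zs <- seq(0, 1, length.out = z_points)
  invadable <- function(alpha) {
    model <- power_tradeoff(alpha)
    W_star <- solve_uniform_ess(graph, lambda, model)$W_star
    fv <- model$f(zs); hv <- model$h(zs)
    for (p in p_grid) {
      EFH <- outer(p * fv * hv, (1 - p) * fv * hv, "+")
      EF <- outer(p * fv, (1 - p) * fv, "+")
      EH <- outer(p * hv, (1 - p) * hv, "+")
      best <- max(n * ((1 - lambda) * EFH + lambda * EF * EH))
      if (best > W_star + indicator_tol) return(TRUE)
    }
    FALSE
  }
  lo <- alpha_range[1]
  hi <- alpha_range[2]
  if (invadable(lo)) return(lo)
  if (!invadable(hi)) {
    warning("no invasion anywhere in alpha_range; returning NA")
    return(NA_real_)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (invadable(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
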