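#' Shareability-by-return-shape phase diagrams
#'
#' Sweeps a grid over the shareability `lambda` and the return exponent
#' `alpha` for a chosen group structure and coordination mode, recording at
#' each grid point whether a division-of-labour mutant can invade uniform
#' cooperation, by which route, and the size of the fitness benefit of the
#' best division of labour (relative to uniform, 0 where not invadable).
#'
#' In `"coordinated"` mode cells know their position: the structure's
#' canonical role partition is analysed with [classify_invasion()] and
#' [optimal_specialisation()] (filament: alternating roles; branching:
#' degree-2 edge cells are helpers; well-mixed: an even split; `file`:
#' the spectral bipartition for regular graphs, otherwise roles by
#' degree). In `"random"` mode roles are uncoordinated: invasion means
#' some `(p, z_h, z_r)` on a search grid achieves a higher closed-form
#' expected fitness than the uniform ES strategy, and the only available
#' route is an accelerating return.
#'
#' @param structure one of `"filament"`, `"branching"`, `"well_mixed"`,
#'   `"file"`.
#' @param mode `"coordinated"` or `"random"`.
#' @param lambda_grid,alpha_grid numeric grids within `(0, 1]` and
#'   `(0, 2]`.
#' @param n cell count for filament and well-mixed structures.
#' @param n_node node-cell count for the branching structure.
#' @param periodic close the filament into a cycle (default).
#' @param edges path to an edge-list file when `structure = "file"`.
#' @param n_h helper count for the well-mixed canonical split (default
#'   `floor(n / 2)`).
#' @param grid_n benefit-optimisation grid points per axis (coordinated
#'   mode).
#' @param p_grid,z_points random-mode search grid (see
#'   [critical_alpha_random()]).
#' @param tol strictly-positive margin for the random-mode invasion
#'   indicator.
#' @return An object of class `phase_diagram`: the grids plus
#'   `invadable` (logical matrix), `benefit` (numeric matrix) and
#'   `scenario` (character matrix), all `length(lambda_grid) x
#'   length(alpha_grid)`.
#' @examples
#' pd <- sweep_phase("filament", "coordinated",
#'                   lambda_grid = seq(0.2, 1, by = 0.2),
#'                   alpha_grid = c(0.5, 1), n = 6, grid_n = 51)
#' pd$invadable
#' @export
sweep_phase <- function(structure = c("filament", "branching", "well_mixed",
                                      "file"),
                        mode = c("coordinated", "random"),
                        lambda_grid, alpha_grid,
                        n = 12, n_node = 4, periodic = TRUE, edges = NULL,
                        n_h = NULL, grid_n = 101,
                        p_grid = seq(0.1, 0.9, by = 0.1), z_points = 101,
                        tol = 1e-9) {
  structure_id <- match.arg(structure)
  mode <- match.arg(mode)
  if (any(lambda_grid < 0) || any(lambda_grid > 1) ||
      any(alpha_grid <= 0) || any(alpha_grid > 2)) {
    stop("config error: grids must lie within (0, 1] x (0, 2]", call. = FALSE)
  }
  built <- build_structure(structure_id, n = n, n_node = n_node,
                           periodic = periodic, edges = edges, n_h = n_h)
  g <- built$graph
  cs <- built$cs
  nl <- length(lambda_grid)
  na <- length(alpha_grid)
  inv <- matrix(FALSE, nl, na)
  ben <- matrix(0, nl, na)
  scn <- matrix("none", nl, na)
  zs <- seq(0, 1, length.out = z_points)
  for (i in seq_len(nl)) {
    lam <- lambda_grid[i]
    for (j in seq_len(na)) {
      model <- power_tradeoff(alpha_grid[j])
      if (mode == "coordinated") {
        rp <- classify_invasion(cs, lam, model, optimise = FALSE)
        inv[i, j] <- rp$invadable
        scn[i, j] <- rp$scenario
        if (rp$invadable) {
          opt <- optimal_specialisation(cs, lam, model, grid_n = grid_n)
          ben[i, j] <- opt$benefit
        }
      } else {
        W_star <- solve_uniform_ess(g, lam, model)$W_star
        fv <- model$f(zs); hv <- model$h(zs)
        best <- -Inf
        for (p in p_grid) {
          EFH <- outer(p * fv * hv, (1 - p) * fv * hv, "+")
          EF <- outer(p * fv, (1 - p) * fv, "+")
          EH <- outer(p * hv, (1 - p) * hv, "+")
          best <- max(best,
                      max(g$n * ((1 - lam) * EFH + lam * EF * EH)))
        }
        if (best > W_star + tol) {
          inv[i, j] <- TRUE
          scn[i, j] <- "accelerating_returns"
          ben[i, j] <- max(0, best / W_star - 1)
        }
      }
    }
  }
  out <- list(structure = structure_id, mode = mode,
              lambda_grid = lambda_grid, alpha_grid = alpha_grid,
              invadable = inv, benefit = ben, scenario = scn)
  class(out) <- "phase_diagram"
  out
}

#' Canonical graph and role partition for a built-in structure
#'
#' Convenience constructor used by [sweep_phase()] and the command-line
#' front end: builds the named structure and its canonical
#' helper/reproductive partition (filament: alternating; branching: edge
#' cells help; well-mixed: an even split; `file`: spectral bipartition for
#' regular graphs, otherwise roles by degree).
#'
#' @param structure_id one of `"filament"`, `"branching"`, `"well_mixed"`,
#'   `"file"`.
#' @inheritParams sweep_phase
#' @return List with the [group_graph()] (`graph`) and its
#'   [classify_partition()] summary (`cs`).
#' @export
build_structure <- function(structure_id, n = 12, n_node = 4, periodic = TRUE,
                            edges = NULL, n_h = NULL) {
  g <- switch(structure_id,
    filament = filament_graph(n, periodic = periodic),
    branching = branching_graph(n_node),
    well_mixed = well_mixed_graph(n),
    file = {
      if (is.null(edges)) {
        stop("config error: structure 'file' needs an edge-list path",
             call. = FALSE)
      }
      read_edge_list(edges)
    }
  )
  roles <- switch(structure_id,
    filament = alternating_roles(g),
    branching = roles_by_degree(g),
    well_mixed = {
      k <- if (is.null(n_h)) floor(g$n / 2) else n_h
      role_assignment(rep(c("helper", "reproductive"), c(k, g$n - k)))
    },
    file = {
      if (length(unique(g$degrees)) == 1) {
        bipartition_measure(g)$bipartition
      } else {
        roles_by_degree(g)
      }
    }
  )
  list(graph = g, cs = classify_partition(g, roles))
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf(
    "phase_diagram: %s, %s mode, %d x %d grid (lambda x alpha), %d%% invadable\n",
    x$structure, x$mode, length(x$lambda_grid), length(x$alpha_grid),
    round(100 * mean(x$invadable))))
  invisible(x)
}

#' Export and re-import phase diagrams as CSV
#'
#' Writes a long-format CSV with header
#' `structure,mode,lambda,alpha,invadable,scenario,benefit`, one row per
#' grid point, sorted by `(lambda, alpha)`. Numeric fields are written
#' with full precision so a re-import reproduces the diagram exactly.
#'
#' @param diagram a [sweep_phase()] result.
#' @param path output (or input) CSV path.
#' @return `export_phase()` returns `path` invisibly; `read_phase()`
#'   returns a `phase_diagram`.
#' @export
export_phase <- function(diagram, path) {
  stopifnot(inherits(diagram, "phase_diagram"))
  grid <- expand.grid(alpha = diagram$alpha_grid,
                      lambda = diagram$lambda_grid)
  # matrices are lambda x alpha; expand.grid varies alpha fastest, matching
  # row-major traversal of each lambda row
  df <- data.frame(
    structure = diagram$structure,
    mode = diagram$mode,
    lambda = sprintf("%.17g", grid$lambda),
    alpha = sprintf("%.17g", grid$alpha),
    invadable = as.vector(t(diagram$invadable)),
    scenario = as.vector(t(diagram$scenario)),
    benefit = sprintf("%.17g", as.vector(t(diagram$benefit))),
    stringsAsFactors = FALSE
  )
  ord <- order(as.numeric(df$lambda), as.numeric(df$alpha))
  utils::write.table(df[ord, ], path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname export_phase
#' @export
read_phase <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("structure", "mode", "lambda", "alpha", "invadable", "scenario",
            "benefit")
  if (!all(need %in% names(df))) {
    stop("not a phase-diagram CSV (missing columns)", call. = FALSE)
  }
  lg <- sort(unique(df$lambda))
  ag <- sort(unique(df$alpha))
  df <- df[order(match(df$lambda, lg), match(df$alpha, ag)), ]
  shape <- function(v) matrix(v, length(lg), length(ag), byrow = TRUE)
  out <- list(structure = df$structure[1], mode = df$mode[1],
              lambda_grid = lg, alpha_grid = ag,
              invadable = shape(df$invadable),
              benefit = shape(df$benefit),
              scenario = shape(df$scenario))
  class(out) <- "phase_diagram"
  out
}
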