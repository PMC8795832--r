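#' Annealing configuration
#'
#' Generic parameters of the simulated-annealing reconstruction engine.
#' Defaults follow the benchmark protocol used throughout the package:
#' initial temperature 0.1, final temperature 1.5e-3, a constant-temperature
#' slab of 1000 iterations, 256 intensity levels, and an iteration budget of
#' 2e5 for 8x8 grids and 8e5 for larger ones (chosen at run time when
#' \code{n_iter} is \code{NULL}).
#'
#' @param cost Cost function identifier (see [cost_function_ids]).
#' @param t0 Initial temperature (> \code{tn}).
#' @param tn Final temperature (> 0). The colder operating point 1e-6
#'   can be passed here directly.
#' @param n_iter Iteration budget N, or \code{NULL} to choose by grid side.
#' @param slab Iterations per constant-temperature slab.
#' @param intensity_levels Size of the quantized intensity lattice.
#' @param seed Integer seed for the proposal/acceptance stream.
#' @param stop_tolerance Early-stopping threshold: at a slab boundary the
#'   run stops when the best-cost improvement over the past slab falls
#'   below \code{stop_tolerance} times the current best cost (error-type
#'   costs only). 0 disables early stopping, leaving the pure
#'   iteration-count rule.
#' @return An object of class \code{anneal_config}.
#' @export
anneal_config <- function(cost = "RMSLE", t0 = 0.1, tn = 1.5e-3,
                          n_iter = NULL, slab = 1000L,
                          intensity_levels = 256L, seed = 1L,
                          stop_tolerance = 0.1) {
  cost <- match_cost_id(cost)
  if (!(tn > 0 && tn < t0)) stop("need 0 < tn < t0")
  if (slab < 1L) stop("slab must be >= 1")
  if (!is.null(n_iter)) {
    n_iter <- as.integer(n_iter)
    if (n_iter < slab) stop("need n_iter >= slab >= 1")
  }
  if (stop_tolerance < 0) stop("stop_tolerance must be >= 0")
  structure(list(cost = cost, t0 = t0, tn = tn, n_iter = n_iter,
                 slab = as.integer(slab),
                 intensity_levels = as.integer(intensity_levels),
                 seed = as.integer(seed), stop_tolerance = stop_tolerance),
            class = "anneal_config")
}

default_n_iter <- function(cfg, side) {
  if (!is.null(cfg$n_iter)) return(cfg$n_iter)
  if (side <= 8L) 200000L else 800000L
}

#' Annealing temperature schedule
#'
#' The hyperbolic-secant cooling profile
#' \eqn{T_k = (T_0 - T_N)/\cosh(10 k'/N) + T_N}, where \eqn{k'} is \eqn{k}
#' truncated to the start of its constant-temperature slab. \eqn{T_0} is
#' attained exactly at \eqn{k = 0} and \eqn{T_N} approached within about
#' \eqn{10^{-5}} at \eqn{k = N}.
#'
#' @param k Iteration index (vectorized), \code{0 <= k <= N}.
#' @param cfg An [anneal_config()] with non-NULL \code{n_iter}.
#' @return Temperature(s) at \code{k}.
#' @export
temperature_at <- function(k, cfg) {
  if (is.null(cfg$n_iter)) stop("cfg$n_iter must be set")
  if (any(k < 0) || any(k > cfg$n_iter))
    stop("iteration index outside [0, N]")
  ks <- (k %/% cfg$slab) * cfg$slab
  (cfg$t0 - cfg$tn) / cosh(10 * ks / cfg$n_iter) + cfg$tn
}

#' Metropolis acceptance rule
#'
#' Downhill moves (\code{d_cost < 0}) are always accepted; uphill moves are
#' accepted with probability \eqn{\exp(-\Delta C / T_k)} against a uniform
#' draw from the current RNG stream.
#'
#' @param d_cost Cost change of the proposed move.
#' @param temperature Current temperature (> 0).
#' @return Logical: accept the move.
#' @export
metropolis_accept <- function(d_cost, temperature) {
  if (temperature <= 0) stop("temperature must be positive")
  if (d_cost < 0) return(TRUE)
  runif(1) < exp(-d_cost / temperature)
}

## ---- explicit annealing state (reference engine and unit surface) -------

#' Initialize an annealing state
#'
#' Builds the explicit state the reference engine iterates on: the
#' quantized estimate, its postulated sinogram (maintained incrementally
#' afterwards), and the current cost.
#'
#' @param measured Measured [sinogram].
#' @param template Starting estimate (square matrix in \[0, 1\]).
#' @param cfg An [anneal_config()].
#' @return An environment of class \code{anneal_state} with fields
#'   \code{f} (integer level matrix), \code{pp} (postulated sinogram
#'   values), \code{cost}, \code{k}, \code{best_f}, \code{best_cost},
#'   \code{bin_idx}, plus the config and geometry.
#' @export
sa_state_init <- function(measured, template, cfg) {
  stopifnot(inherits(measured, "sinogram"))
  side <- nrow(template)
  if (side != ncol(template)) stop("template must be square")
  if (side != measured$geometry$side)
    stop("template side does not match sinogram geometry")
  L <- cfg$intensity_levels
  f <- matrix(as.integer(round(unclass(template) * (L - 1))), side, side)
  est <- f / (L - 1)
  pp <- radon_forward(est, measured$geometry)
  cost <- aggregate_cost(cfg$cost, measured, pp)
  st <- new.env(parent = emptyenv())
  st$cfg <- cfg
  st$geom <- measured$geometry
  st$pm <- measured
  st$f <- f
  st$pp <- pp$values
  st$cost <- cost
  st$k <- 0L
  st$best_f <- f
  st$best_cost <- cost
  st$bin_idx <- radon_bin_indices(measured$geometry)
  st$side <- side
  class(st) <- "anneal_state"
  st
}

#' Propose a random single-pixel move
#'
#' Draws a uniformly random pixel and a uniformly random quantized
#' intensity level from the current RNG stream.
#'
#' @param state An \code{anneal_state}.
#' @return List with \code{row}, \code{col}, \code{level} (0-based level
#'   index) and \code{value} (level mapped to \[0, 1\]).
#' @export
propose_move <- function(state) {
  n <- state$side
  L <- state$cfg$intensity_levels
  idx0 <- min(floor(runif(1) * n * n), n * n - 1)
  level <- min(floor(runif(1) * L), L - 1)
  list(row = as.integer(idx0 %% n) + 1L, col = as.integer(idx0 %/% n) + 1L,
       level = as.integer(level), value = level / (L - 1))
}

#' Evaluate a move incrementally (without committing)
#'
#' Updates the postulated sinogram by adding the intensity increment of the
#' touched pixel to the single affected bin of every view, and returns the
#' resulting cost change. The state itself is untouched; committing or
#' discarding is the caller's choice (a rejected candidate costs nothing).
#'
#' @param state An \code{anneal_state}.
#' @param move A move from [propose_move()].
#' @return List with \code{pp} (candidate sinogram values), \code{cost}
#'   (candidate cost), \code{d_cost}.
#' @export
apply_move <- function(state, move) {
  L <- state$cfg$intensity_levels
  old <- state$f[move$row, move$col] / (L - 1)
  d <- move$value - old
  pp2 <- state$pp
  if (d != 0) {
    pix <- (move$col - 1L) * state$side + move$row
    bins <- state$bin_idx[pix, ]
    for (m in seq_along(bins)) pp2[bins[m], m] <- pp2[bins[m], m] + d
  }
  cost2 <- if (d == 0) state$cost
           else aggregate_cost(state$cfg$cost, state$pm,
                               new_sinogram(pp2, state$geom))
  list(pp = pp2, cost = cost2, d_cost = cost2 - state$cost)
}

#' Commit an evaluated move to the state
#'
#' @param state An \code{anneal_state}.
#' @param move The move proposed by [propose_move()].
#' @param applied The evaluation returned by [apply_move()].
#' @return The state, invisibly (modified in place).
#' @export
commit_move <- function(state, move, applied) {
  force(applied)  # evaluate against the pre-move state
  state$f[move$row, move$col] <- move$level
  state$pp <- applied$pp
  state$cost <- applied$cost
  if (applied$cost < state$best_cost) {
    state$best_cost <- applied$cost
    state$best_f <- state$f
  }
  invisible(state)
}

## guard the degenerate cost configurations that can be detected up front
check_cost_feasible <- function(cost, measured) {
  if (cost %in% c("RSE", "RAE")) {
    cv <- apply(measured$values, 2L, function(v) diff(range(v)) == 0)
    if (any(cv))
      stop("configuration error: ", cost, " is undefined on a sinogram ",
           "with a constant view")
  }
  if (cost == "RMSLE" && any(measured$values < 0))
    stop("configuration error: RMSLE requires a non-negative sinogram")
  invisible(TRUE)
}

#' Simulated-annealing image reconstruction
#'
#' Reconstructs a cross-section from a sparse-view sinogram by simulated
#' annealing: starting from the wavelet-multiscale FBP template, single
#' pixels are repeatedly redrawn on the quantized intensity lattice, the
#' postulated sinogram is updated incrementally (one bin per view), and
#' moves are accepted by the Metropolis rule under the hyperbolic-secant
#' cooling schedule of [temperature_at()]. The best estimate seen is
#' tracked and returned.
#'
#' @param measured Measured [sinogram].
#' @param cfg An [anneal_config()].
#' @param template Starting estimate; \code{NULL} builds the
#'   wavelet-multiscale template from the sinogram via [build_template()].
#' @param side Reconstruction grid side (defaults to the sinogram
#'   geometry's side).
#' @param engine \code{"cpp"} (compiled, default) or \code{"r"} (reference
#'   implementation; identical draw protocol, used for cross-validation).
#' @return An object of class \code{sa_recon}: fields \code{estimate}
#'   (best image), \code{final} (last accepted image), \code{best_cost},
#'   \code{cost} (final current cost), \code{trace} (per-slab data frame:
#'   \code{k}, \code{temperature}, \code{cost}, \code{best_cost},
#'   \code{acceptance_rate}), \code{iterations}, \code{accepted},
#'   \code{config}, \code{measured}, \code{template}.
#' @seealso [plot.sa_recon()], [residuals.sa_recon()], [benchmark_costs()]
#' @export
run_sa <- function(measured, cfg = anneal_config(), template = NULL,
                   side = NULL, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(measured, "sinogram"))
  if (is.null(side)) side <- measured$geometry$side
  check_cost_feasible(cfg$cost, measured)
  if (is.null(template))
    template <- build_template(measured, side,
                               quantize = cfg$intensity_levels)$image
  if (nrow(template) != side) stop("template side mismatch")
  cfg$n_iter <- default_n_iter(cfg, side)

  res <- with_seed(cfg$seed, function() {
    if (engine == "cpp") run_sa_engine_cpp(measured, template, cfg)
    else run_sa_engine_r(measured, template, cfg)
  })

  L <- cfg$intensity_levels
  trace <- as.data.frame(res$trace)
  names(trace) <- c("k", "temperature", "cost", "best_cost",
                    "acceptance_rate")
  structure(list(
    estimate = structure(res$best_f / (L - 1),
                         class = c("image_grid", "matrix")),
    final = structure(res$f / (L - 1), class = c("image_grid", "matrix")),
    best_cost = res$best_cost, cost = res$cost, trace = trace,
    iterations = res$iterations, accepted = res$accepted,
    config = cfg, measured = measured, template = template),
    class = "sa_recon")
}

run_sa_engine_cpp <- function(measured, template, cfg) {
  L <- cfg$intensity_levels
  f0 <- matrix(as.integer(round(unclass(template) * (L - 1))),
               nrow(template), ncol(template))
  B <- radon_bin_indices(measured$geometry)
  sa_engine(measured$values, B, nrow(template), measured$geometry$n_bins,
            L, cfg$t0, cfg$tn, cfg$n_iter, cfg$slab,
            cost_id_code(cfg$cost),
            cost_orientation(cfg$cost) == "error", cfg$stop_tolerance, f0)
}

## reference engine: same draw protocol as the compiled one, used by the
## parity and invariant tests
run_sa_engine_r <- function(measured, template, cfg) {
  st <- sa_state_init(measured, template, cfg)
  n_slabs <- ceiling(cfg$n_iter / cfg$slab)
  trace <- matrix(NA_real_, n_slabs + 1L, 5L)
  trace[1L, ] <- c(0, temperature_at(0L, cfg), st$cost, st$best_cost, NA)
  accepted_total <- 0L; accepted_slab <- 0L; row <- 2L
  prev_best <- st$best_cost
  k <- 0L
  stop_early <- FALSE
  while (k < cfg$n_iter && !stop_early) {
    temp <- temperature_at(k, cfg)
    move <- propose_move(st)
    app <- apply_move(st, move)
    if (metropolis_accept(app$d_cost, temp)) {
      commit_move(st, move, app)
      accepted_total <- accepted_total + 1L
      accepted_slab <- accepted_slab + 1L
    }
    k <- k + 1L
    if (k %% cfg$slab == 0L || k == cfg$n_iter) {
      trace[row, ] <- c(k, temp, st$cost, st$best_cost,
                        accepted_slab / cfg$slab)
      row <- row + 1L
      if (cfg$stop_tolerance > 0 &&
          cost_orientation(cfg$cost) == "error" &&
          (prev_best - st$best_cost) < cfg$stop_tolerance * st$best_cost)
        stop_early <- TRUE
      prev_best <- st$best_cost
      accepted_slab <- 0L
    }
  }
  list(f = st$f, best_f = st$best_f, pp = st$pp, cost = st$cost,
       best_cost = st$best_cost, trace = trace[seq_len(row - 1L), , drop = FALSE],
       iterations = k, accepted = accepted_total)
}
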