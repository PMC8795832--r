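#' Benchmark the cost-function bank on a phantom
#'
#' Runs the full annealing reconstruction repeatedly for each requested
#' cost function against the sinogram of a known phantom, and summarizes
#' reconstruction quality (PSNR, relative Euclidean error, WPSNR; mean and
#' n-1 standard deviation over repetitions) together with run times and
#' per-run convergence traces. Every per-run seed is derived from the
#' master seed in \code{cfg}, so the whole table is deterministic.
#'
#' @param phantom Ground-truth image (square matrix in \[0, 1\]).
#' @param cfg An [anneal_config()]; its \code{cost} field is ignored in
#'   favour of \code{cost_ids}, its \code{seed} is the master seed. For the
#'   fixed-iteration benchmark protocol pass \code{stop_tolerance = 0}.
#' @param cost_ids Cost identifiers to benchmark (default: all seven).
#' @param repetitions Repetitions per cost function (>= 2).
#' @param n_views Number of projection views (default 18, the ultralow-dose
#'   setting).
#' @return A data frame of class \code{sa_benchmark} with one row per cost
#'   id (columns \code{cost}, \code{psnr_mean}, \code{psnr_sd},
#'   \code{eue_mean}, \code{eue_sd}, \code{wpsnr_mean}, \code{wpsnr_sd},
#'   \code{time_mean}) and attributes \code{runs} (list of per-run records
#'   with traces) and \code{geometry}.
#' @export
benchmark_costs <- function(phantom, cfg = anneal_config(stop_tolerance = 0),
                            cost_ids = cost_function_ids,
                            repetitions = 20L, n_views = 18L) {
  if (length(cost_ids) == 0L) stop("empty cost list")
  cost_ids <- vapply(cost_ids, match_cost_id, character(1))
  repetitions <- as.integer(repetitions)
  if (repetitions < 2L) stop("repetitions must be >= 2")
  side <- nrow(phantom)
  geom <- projection_geometry(side, n_views)
  measured <- radon_forward(phantom, geom)
  template <- build_template(measured, side,
                             quantize = cfg$intensity_levels)$image
  seeds <- with_seed(cfg$seed, function()
    matrix(sample.int(.Machine$integer.max - 1L,
                      length(cost_ids) * repetitions),
           nrow = repetitions))
  runs <- list()
  rows <- lapply(seq_along(cost_ids), function(i) {
    id <- cost_ids[i]
    qs <- matrix(NA_real_, repetitions, 3L)
    times <- numeric(repetitions)
    for (r in seq_len(repetitions)) {
      cfg_r <- cfg
      cfg_r$cost <- id
      cfg_r$seed <- seeds[r, i]
      t0 <- proc.time()[["elapsed"]]
      rec <- run_sa(measured, cfg_r, template = template)
      times[r] <- proc.time()[["elapsed"]] - t0
      q <- quality_report(phantom, rec$estimate)
      qs[r, ] <- c(q$psnr, q$eue, q$wpsnr)
      runs[[paste(id, r, sep = ".")]] <<- list(
        cost = id, rep = r, seed = cfg_r$seed, quality = q,
        trace = rec$trace, best_cost = rec$best_cost)
    }
    data.frame(cost = id, reps = repetitions,
               psnr_mean = mean(qs[, 1]), psnr_sd = sd(qs[, 1]),
               eue_mean = mean(qs[, 2]), eue_sd = sd(qs[, 2]),
               wpsnr_mean = mean(qs[, 3]), wpsnr_sd = sd(qs[, 3]),
               time_mean = mean(times))
  })
  out <- do.call(rbind, rows)
  attr(out, "runs") <- runs
  attr(out, "geometry") <- geom
  class(out) <- c("sa_benchmark", class(out))
  out
}

#' @export
print.sa_benchmark <- function(x, ...) {
  cat(sprintf("Cost-function benchmark (%d repetitions each)\n", x$reps[1]))
  df <- as.data.frame(x)
  df[-(1:2)] <- lapply(df[-(1:2)], function(v) round(v, 2))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Normalized convergence trace
#'
#' Converts a cost series into the standard convergence diagnostic: the
#' best-so-far cost divided by the initial cost. The first value is always
#' 1 and the series is non-increasing.
#'
#' @param trace Numeric cost series (for example the per-slab \code{cost}
#'   or \code{best_cost} column of an \code{sa_recon} trace).
#' @return Numeric vector of the same length.
#' @export
convergence_trace <- function(trace) {
  if (length(trace) == 0L) stop("empty trace")
  cummin(trace) / trace[1]
}
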