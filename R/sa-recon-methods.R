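#' @export
print.sa_recon <- function(x, ...) {
  cat(sprintf(
    "Simulated-annealing reconstruction (%d x %d, cost %s)\n",
    nrow(x$estimate), ncol(x$estimate), x$config$cost))
  cat(sprintf("  iterations: %d of %d (%.1f%% accepted)\n",
              x$iterations, x$config$n_iter,
              100 * x$accepted / max(x$iterations, 1L)))
  cat(sprintf("  best cost:  %.6g\n", x$best_cost))
  invisible(x)
}

#' Summarize a simulated-annealing reconstruction
#'
#' @param object An \code{sa_recon} object.
#' @param reference Optional ground-truth image; when supplied, the
#'   summary includes the [quality_report()] of the best estimate.
#' @param ... Unused.
#' @return The object's key figures, invisibly; printed as a side effect.
#' @export
summary.sa_recon <- function(object, reference = NULL, ...) {
  print(object)
  cat(sprintf("  temperature: %.3g -> %.3g over %d-iteration slabs\n",
              object$config$t0, object$config$tn, object$config$slab))
  tr <- convergence_trace(object$trace$best_cost)
  cat(sprintf("  normalized best cost at stop: %.4f\n", tr[length(tr)]))
  out <- list(best_cost = object$best_cost,
              normalized_final = tr[length(tr)])
  if (!is.null(reference)) {
    q <- quality_report(reference, object$estimate)
    print(q)
    out$quality <- q
  }
  invisible(out)
}

#' Postulated sinogram of the best estimate
#'
#' @param object An \code{sa_recon} object.
#' @param ... Unused.
#' @return \code{fitted}: the forward projection of the best estimate, as
#'   a [sinogram]; \code{residuals}: measured minus fitted values
#'   (\code{n_bins x n_views} matrix).
#' @export
fitted.sa_recon <- function(object, ...) {
  radon_forward(object$estimate, object$measured$geometry)
}

#' @rdname fitted.sa_recon
#' @export
residuals.sa_recon <- function(object, ...) {
  object$measured$values - fitted(object)$values
}

#' Plot the annealing convergence trace
#'
#' Draws the per-slab normalized best cost (best-so-far cost divided by
#' its initial value) against iteration count, the standard convergence
#' diagnostic for the annealer.
#'
#' @param x An \code{sa_recon} object.
#' @param ... Passed to [plot()].
#' @return \code{x}, invisibly.
#' @export
plot.sa_recon <- function(x, ...) {
  tr <- x$trace
  plot(tr$k, convergence_trace(tr$best_cost), type = "l",
       xlab = "iteration", ylab = "normalized best cost",
       main = sprintf("SA convergence (%s)", x$config$cost), ...)
  invisible(x)
}
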