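#' The seven projection-domain cost functions
#'
#' Identifiers of the per-view cost functions available to the annealer:
#' two similarity indices (UIQI, SSIM, bounded above by 1) and five error
#' measures (RSE, MAE, RAE, RMSE, RMSLE). [aggregate_cost()] wraps the
#' similarity indices as \code{1 - index} so a single minimizer serves all
#' seven.
#'
#' @format Character vector of the seven identifiers.
#' @export
cost_function_ids <- c("UIQI", "RSE", "SSIM", "MAE", "RAE", "RMSE", "RMSLE")

#' @rdname cost_function_ids
#' @param id A cost function identifier.
#' @return \code{cost_orientation}: \code{"similarity"} or \code{"error"}.
#' @export
cost_orientation <- function(id) {
  id <- match_cost_id(id)
  if (id %in% c("UIQI", "SSIM")) "similarity" else "error"
}

match_cost_id <- function(id) {
  i <- match(toupper(id), cost_function_ids)
  if (is.na(i))
    stop("unknown cost function '", id, "'; valid ids: ",
         paste(cost_function_ids, collapse = ", "))
  cost_function_ids[i]
}

## numeric codes shared with the compiled annealing engine
cost_id_code <- function(id) match(match_cost_id(id), cost_function_ids)

#' Per-view cost between measured and postulated projections
#'
#' Evaluates one view's statistic between the measured projection
#' \code{pm} (the reference) and the postulated projection \code{pp}:
#' \describe{
#'   \item{UIQI}{Wang-Bovik universal image quality index, the three-factor
#'     product of correlation, mean proximity and contrast proximity
#'     (sample moments); equals \eqn{4\sigma_{xy}\bar x\bar y /
#'     ((\sigma_x^2+\sigma_y^2)(\bar x^2+\bar y^2))}.}
#'   \item{RSE}{\eqn{\sum(pm-pp)^2 / \sum(\bar{pm}-pm)^2}.}
#'   \item{SSIM}{luminance--contrast--structure product with stabilizers
#'     \eqn{C_1=(0.01L)^2}, \eqn{C_2=(0.03L)^2}, \eqn{C_3=C_2/2}, where
#'     \eqn{L} is the dynamic range of \code{pm}; the window is the whole
#'     vector (projections are 1-D).}
#'   \item{MAE}{mean absolute difference.}
#'   \item{RAE}{\eqn{\sum|pm-pp| / \sum|\bar{pm}-pm|}.}
#'   \item{RMSE}{root mean squared difference.}
#'   \item{RMSLE}{root mean squared difference of \eqn{\log(1+\cdot)};
#'     requires non-negative projections.}
#' }
#'
#' @param id Cost function identifier (see [cost_function_ids]).
#' @param pm,pp Numeric vectors of equal length (at least 2), finite.
#' @return The view statistic (similarity indices near 1 mean good
#'   agreement; error measures near 0 do).
#' @examples
#' view_cost("MAE", c(1, 3), c(2, 5))   # 1.5
#' view_cost("RMSE", c(0, 0), c(3, 4))  # sqrt(12.5)
#' @export
view_cost <- function(id, pm, pp) {
  id <- match_cost_id(id)
  if (length(pm) != length(pp)) stop("pm and pp must have equal length")
  if (length(pm) < 2L) stop("projections must have length >= 2")
  if (!all(is.finite(pm)) || !all(is.finite(pp)))
    stop("projections must be finite")
  n <- length(pm)
  switch(id,
    UIQI = {
      sx <- sd(pm); sy <- sd(pp)
      if (sx == 0 || sy == 0)
        stop("degenerate input: UIQI undefined for a constant projection")
      mx <- mean(pm); my <- mean(pp)
      if (mx^2 + my^2 == 0)
        stop("degenerate input: UIQI undefined for zero-mean pair")
      sxy <- sum((pm - mx) * (pp - my)) / (n - 1)
      (sxy / (sx * sy)) * (2 * mx * my / (mx^2 + my^2)) *
        (2 * sx * sy / (sx^2 + sy^2))
    },
    RSE = {
      den <- sum((mean(pm) - pm)^2)
      if (den == 0)
        stop("degenerate input: RSE undefined for a constant measured projection")
      sum((pm - pp)^2) / den
    },
    SSIM = {
      L <- diff(range(pm))
      if (L == 0)
        stop("degenerate input: SSIM undefined for a constant measured projection")
      C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2; C3 <- C2 / 2
      mx <- mean(pm); my <- mean(pp)
      sx <- sd(pm); sy <- sd(pp)
      sxy <- sum((pm - mx) * (pp - my)) / (n - 1)
      l <- (2 * mx * my + C1) / (mx^2 + my^2 + C1)
      cc <- (2 * sx * sy + C2) / (sx^2 + sy^2 + C2)
      s <- (sxy + C3) / (sx * sy + C3)
      l * cc * s
    },
    MAE = mean(abs(pm - pp)),
    RAE = {
      den <- sum(abs(mean(pm) - pm))
      if (den == 0)
        stop("degenerate input: RAE undefined for a constant measured projection")
      sum(abs(pm - pp)) / den
    },
    RMSE = sqrt(mean((pm - pp)^2)),
    RMSLE = {
      if (any(pm < 0) || any(pp < 0))
        stop("domain error: RMSLE requires non-negative projections")
      sqrt(mean((log1p(pm) - log1p(pp))^2))
    })
}

#' Aggregate annealing objective over all views
#'
#' The annealing cost \eqn{C_k}: the mean of [view_cost()] over the views
#' of two sinograms with identical geometry. Similarity identifiers are
#' wrapped as \code{1 - mean(index)} so that lower is always better and 0
#' means perfect agreement.
#'
#' @param id Cost function identifier.
#' @param pm_sino Measured [sinogram].
#' @param pp_sino Postulated [sinogram] on the same geometry.
#' @return Non-negative scalar objective (0 iff the sinograms agree, on
#'   non-degenerate input).
#' @export
aggregate_cost <- function(id, pm_sino, pp_sino) {
  id <- match_cost_id(id)
  stopifnot(inherits(pm_sino, "sinogram"), inherits(pp_sino, "sinogram"))
  ga <- pm_sino$geometry; gb <- pp_sino$geometry
  if (ga$n_bins != gb$n_bins || ga$n_views != gb$n_views ||
      !isTRUE(all.equal(ga$angles, gb$angles)))
    stop("sinogram geometry mismatch")
  per_view <- vapply(seq_len(ga$n_views), function(m)
    view_cost(id, pm_sino$values[, m], pp_sino$values[, m]), numeric(1))
  if (cost_orientation(id) == "similarity") 1 - mean(per_view)
  else mean(per_view)
}
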