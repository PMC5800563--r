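#' Place natural cubic spline knots from case exposures
#'
#' Interior knots go at the 20th, 40th, 60th and 80th percentiles (type-7
#' quantiles) of the end-of-follow-up cumulative exposure of the cases
#' (workers who died of lung cancer); boundary knots at the minimum and
#' maximum case exposure.  Outside the boundary knots the natural basis
#' continues linearly.
#'
#' @param case_exposures cumulative exposures (100 WLM units) of the cases.
#' @return an object of class `spline_basis` with elements `interior` and
#'   `boundary`.
#' @export
select_spline_knots <- function(case_exposures) {
  x <- case_exposures[is.finite(case_exposures)]
  .assert(length(x) >= 5L && sum(x > 0) >= 5L,
          "need at least 5 cases with positive cumulative exposure; enlarge the cohort")
  interior <- unname(stats::quantile(x, c(0.2, 0.4, 0.6, 0.8), type = 7))
  boundary <- range(x)
  .assert(!anyDuplicated(interior) && boundary[1L] < boundary[2L],
          "degenerate knots: case exposures have too many ties")
  structure(list(interior = interior, boundary = boundary),
            class = "spline_basis")
}

#' Natural cubic spline basis anchored at zero exposure
#'
#' Evaluates the natural cubic spline basis at `x` and subtracts its value
#' at 0, so that any coefficient vector gives a dose-response with
#' `eta(0) = 0` and the baseline hazard stays identifiable.
#'
#' @param basis a [select_spline_knots()] object.
#' @param x evaluation points (100 WLM units); points beyond the boundary
#'   knots are extended linearly (natural constraint).
#' @return numeric matrix with `length(interior) + 1` columns.
#' @export
spline_basis_matrix <- function(basis, x) {
  B <- splines::ns(x, knots = basis$interior, Boundary.knots = basis$boundary)
  B0 <- splines::ns(0, knots = basis$interior, Boundary.knots = basis$boundary)
  out <- unname(B - matrix(B0, nrow = length(x), ncol = ncol(B), byrow = TRUE))
  attr(out, "extrapolated") <- x < basis$boundary[1L] | x > basis$boundary[2L]
  out
}

#' Posterior exposure-response curve with pointwise credible band
#'
#' Evaluates the fitted dose-response `eta(x)` draw by draw on an exposure
#' grid and returns the pointwise posterior median and equal-tailed 95%
#' band.  For Cox-family fits `eta` is the log hazard ratio; for
#' excess-hazard-ratio fits it is the excess hazard `g(x) - 1`.  Grid
#' points beyond the spline boundary knots are linear extrapolations and
#' flagged.
#'
#' @param fit a `ph_fit` for any disease form.
#' @param grid exposure grid (100 WLM units); default 101 points over the
#'   observed segment range.
#' @return data frame with columns `x`, `median`, `lower`, `upper`,
#'   `extrapolated`; attribute `family` records the scale.
#' @export
exposure_response_curve <- function(fit, grid = NULL) {
  data <- fit$data
  if (is.null(grid))
    grid <- seq(0, attr_range(data), length.out = 101L)
  template <- disease_model(data$form, breakpoint = data$breakpoint,
                            basis = data$basis)
  P <- dose_design(template, grid)
  Eta <- P %*% t(fit$beta)                      # grid x draws
  qs <- apply(Eta, 1L, function(v) c(stats::median(v), .ci95(v)))
  extra <- if (!is.null(data$basis))
    grid < data$basis$boundary[1L] | grid > data$basis$boundary[2L]
  else rep(FALSE, length(grid))
  out <- data.frame(x = grid, median = qs[1L, ], lower = qs[2L, ],
                    upper = qs[3L, ], extrapolated = extra)
  attr(out, "family") <- data$family
  out
}

# largest cumulative exposure represented in the likelihood data
attr_range <- function(data) {
  if (data$form %in% c("D1", "D2")) max(data$seg_X[, 1L])
  else if (data$form %in% c("D5", "D6"))
    max(data$seg_X[, 1L] + data$seg_X[, 2L])
  else max(data$basis$boundary)
}

#' @export
plot.ph_fit <- function(x, grid = NULL, ...) {
  curve <- exposure_response_curve(x, grid)
  ylab <- if (attr(curve, "family") == "cox") "log hazard ratio" else "excess hazard ratio"
  graphics::plot(curve$x, curve$median, type = "l",
                 xlab = "cumulative exposure (100 WLM)", ylab = ylab, ...)
  graphics::lines(curve$x, curve$lower, lty = 2)
  graphics::lines(curve$x, curve$upper, lty = 2)
  invisible(curve)
}
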