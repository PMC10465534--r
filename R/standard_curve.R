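# Standard curves: inducer concentration -> relative promoter activity,
# built from an inducible-GFP control measured on the same plate.

#' Build a standard curve from an inducible-GFP control
#'
#' Computes the mean autofluorescence-subtracted FL/OD of the control at
#' each inducer concentration (the knots). The curve must be monotone
#' non-decreasing; means that decrease beyond `mono_tol` (relative) are
#' pooled by isotonic regression ([stats::isoreg()]) with a warning.
#' Queries interpolate monotonically between knots — piecewise linear by
#' default, or a Hill fit with `rule = "hill"`.
#'
#' @param control either a corrected plate (see [correct_plate()]) whose
#'   `sample` wells are the GFP control, or a data frame with columns
#'   `inducer` and `response` (replicate-level FL/OD).
#' @param channel fluorescence channel of the control reporter.
#' @param rule interpolation rule, `"linear"` (default) or `"hill"` (a
#'   4-parameter Hill curve least-squares fit through the knot means).
#' @param mono_tol relative tolerance for the monotonicity check.
#' @return A `standard_curve` object with fields `conc` (knot
#'   concentrations), `raw_means`, `value` (isotonic-adjusted knot means),
#'   `rule`, and for the Hill rule the fitted coefficients.
#' @seealso [map_inducer_to_activity()], [activity_to_inducer()]
#' @export
build_standard_curve <- function(control, channel = "FL_GFP", rule = "linear",
                                 mono_tol = 1e-8) {
  rule <- match.arg(rule, c("linear", "hill"))
  col <- paste0(channel, "_per_OD_corr")
  if (inherits(control, "corrected_plate") && col %in% names(control)) {
    dat <- control[control$role == "sample" & !control$flagged,
                   c("inducer", col)]
    names(dat) <- c("inducer", "response")
  } else {
    stopifnot(all(c("inducer", "response") %in% names(control)))
    dat <- as.data.frame(control)[, c("inducer", "response")]
  }
  dat <- dat[stats::complete.cases(dat), ]
  conc <- sort(unique(dat$inducer))
  if (length(conc) < 3)
    stop("a standard curve needs >= 3 inducer levels; got ", length(conc))
  means <- vapply(conc, function(cc) mean(dat$response[dat$inducer == cc]),
                  numeric(1))
  value <- means
  scale <- max(abs(means))
  if (any(diff(means) < -mono_tol * scale)) {
    warning("control means are not monotone in the inducer; applying isotonic regression")
    value <- stats::isoreg(conc, means)$yf
  }
  curve <- list(conc = conc, raw_means = means, value = value, rule = rule)
  if (rule == "hill") curve$hill <- fit_hill(conc, value)
  structure(curve, class = "standard_curve")
}

# Least-squares 4-parameter Hill fit: b + (top - b) * c^h / (c50^h + c^h).
fit_hill <- function(conc, value) {
  obj <- function(par) {
    b <- par[1]; top <- par[2]; c50 <- exp(par[3]); h <- exp(par[4])
    pred <- b + (top - b) * conc^h / (c50^h + conc^h)
    sum((pred - value)^2)
  }
  init <- c(min(value), max(value), log(stats::median(conc)), 0)
  fit <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  c(basal = fit$par[1], top = fit$par[2],
    c50 = exp(fit$par[3]), h = exp(fit$par[4]))
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("standard curve (", x$rule, " rule), ", length(x$conc), " knots\n", sep = "")
  print(data.frame(inducer = x$conc, mean = x$raw_means, value = x$value),
        row.names = FALSE)
  invisible(x)
}

#' Map an inducer concentration to relative promoter activity
#'
#' Interpolates the standard curve at `concentration` and normalises so the
#' highest-induction knot maps to activity 1.0 (the normalisation anchor is
#' the same plate's maximally induced GFP control). Concentrations above the
#' highest knot are refused (no extrapolation); concentrations below the
#' lowest knot return the basal (lowest-knot) activity.
#'
#' @param curve a [build_standard_curve()] object.
#' @param concentration inducer concentration(s), each in `[0, max(knots)]`.
#' @return Relative promoter activity in `[0, 1]`, monotone in concentration.
#' @export
map_inducer_to_activity <- function(curve, concentration) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(!is.finite(concentration)) || any(concentration < 0) ||
      any(concentration > max(curve$conc) * (1 + 1e-12)))
    stop("concentration out of range [0, ", max(curve$conc),
         "]: extrapolation beyond the standard curve is refused")
  anchor <- curve$value[length(curve$value)]
  if (anchor <= 0) stop("top knot of the standard curve is not positive")
  raw <- if (curve$rule == "hill") {
    hc <- curve$hill
    hc["basal"] + (hc["top"] - hc["basal"]) *
      concentration^hc["h"] / (hc["c50"]^hc["h"] + concentration^hc["h"])
  } else {
    stats::approx(curve$conc, curve$value, xout = pmax(concentration, curve$conc[1]),
                  method = "linear", rule = 2)$y
  }
  unname(raw) / anchor
}

#' Invert a standard curve: activity back to inducer concentration
#'
#' Inverse query of the monotone (linear-rule) curve; a knot's activity maps
#' back to the knot concentration. Flat stretches return the lowest
#' concentration attaining the activity.
#'
#' @param curve a linear-rule [build_standard_curve()] object.
#' @param activity relative promoter activity in `[basal, 1]`.
#' @return Inducer concentration(s).
#' @export
activity_to_inducer <- function(curve, activity) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$rule != "linear")
    stop("inverse queries are implemented for the linear rule only")
  anchor <- curve$value[length(curve$value)]
  target <- activity * anchor
  lo <- min(curve$value); hi <- max(curve$value)
  if (any(target < lo - 1e-9 * hi) || any(target > hi * (1 + 1e-12)))
    stop("activity outside the range spanned by the standard curve")
  vapply(target, function(tv) {
    i <- which(curve$value >= tv - 1e-12 * hi)[1]
    if (i == 1) return(curve$conc[1])
    v0 <- curve$value[i - 1]; v1 <- curve$value[i]
    if (v1 == v0) return(curve$conc[i - 1])
    curve$conc[i - 1] + (tv - v0) / (v1 - v0) * (curve$conc[i] - curve$conc[i - 1])
  }, numeric(1))
}
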