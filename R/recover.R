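# Least-squares recovery of model parameters from a (synthetic or real)
# copy-sweep plate.

#' Recover model parameters from a corrected copy-sweep dataset
#'
#' Fits the closed-form steady state `gain * G_star(u, n; eps, K, lam, ...)`
#' to the condition means of autofluorescence-subtracted FL/OD by least
#' squares, with a chosen subset of \{`eps`, `K`, `lam`, `gain`\} free and
#' everything else fixed at `known`. Conditions are identified by the plate
#' columns `copies` and `u` (ground-truth or standard-curve-mapped promoter
#' activity in model input units).
#'
#' `eps` and `gain` are jointly identifiable only when the design spans
#' several copy levels (their product is all that a single level
#' constrains); that degenerate request is refused.
#'
#' @param dataset a plate (raw or already corrected); raw plates are passed
#'   through [correct_plate()].
#' @param known a [model_params()] object holding the fixed parameters.
#' @param free character subset of `c("eps", "K", "lam", "gain")`.
#' @param gain known calibration gain (FL/OD per model a.u.) when `"gain"`
#'   is not free.
#' @param channel fluorescence channel to fit.
#' @return A list with `estimates` (named vector of the free parameters),
#'   `se` (approximate standard errors from the numerical Hessian), `ci`
#'   (95% normal intervals), `rss`, and `fitted` (condition means and
#'   predictions).
#' @examples
#' plate <- generate_copy_sweep(noise = noise_model(cv_bio = 0, sd_read = 0, od_cv = 0))
#' recover_parameters(plate, known = model_params(), free = "lam")$estimates
#' @export
recover_parameters <- function(dataset, known = model_params(),
                               free = c("eps", "lam"), gain = 1e4,
                               channel = "FL_GFP") {
  allowed <- c("eps", "K", "lam", "gain")
  if (!length(free) || !all(free %in% allowed))
    stop("free must be a non-empty subset of ", paste(allowed, collapse = ", "))
  corrected <- if (inherits(dataset, "corrected_plate")) dataset
               else correct_plate(dataset)
  col <- paste0(channel, "_per_OD_corr")
  sel <- corrected$role == "sample" & !corrected$flagged &
    !is.na(corrected$copies) & !is.na(corrected$u)
  if (!is.null(corrected$construct)) sel <- sel & corrected$construct == "array"
  dat <- corrected[sel, c("copies", "u", col)]
  names(dat)[3] <- "y"
  agg <- stats::aggregate(y ~ copies + u, dat, mean)
  if (all(c("eps", "gain") %in% free) && length(unique(agg$copies)) < 2)
    stop("eps and gain are not jointly identifiable from a single copy level")
  if (nrow(agg) < length(free))
    stop("fewer conditions than free parameters")

  lower <- c(eps = 1e-6, K = 1e-6, lam = 0, gain = 1e-6)
  upper <- c(eps = 1, K = Inf, lam = 1, gain = Inf)
  start <- c(eps = known$eps, K = known$K, lam = known$lam, gain = gain)
  # mild perturbation so zero-gradient starts at box corners are avoided
  start[free] <- pmin(pmax(start[free] * 0.8 + 0.01, lower[free] * 2),
                      ifelse(is.finite(upper[free]), upper[free] * 0.98, start[free] * 2))

  predict_means <- function(th) {
    p <- known
    for (f in setdiff(free, "gain")) p[[f]] <- th[[f]]
    g <- if ("gain" %in% free) th[["gain"]] else gain
    p <- validate_model_params(p)
    g * mapply(function(n, u)
      steady_state(with_params(p, n = n, u = u))$G_star, agg$copies, agg$u)
  }
  obj <- function(th) {
    names(th) <- free
    sum((predict_means(th) - agg$y)^2)
  }
  fit <- stats::optim(start[free], obj, method = "L-BFGS-B",
                      lower = lower[free], upper = upper[free],
                      control = list(factr = 1e4, maxit = 500), hessian = TRUE)
  est <- fit$par
  n_cond <- nrow(agg)
  sigma2 <- fit$value / max(1, n_cond - length(free))
  se <- rep(NA_real_, length(free))
  h <- try(solve(fit$hessian), silent = TRUE)
  if (!inherits(h, "try-error")) {
    v <- 2 * sigma2 * diag(as.matrix(h))
    se <- ifelse(v > 0, sqrt(v), NA_real_)
  }
  names(se) <- free
  ci <- cbind(lower = est - 1.96 * se, upper = est + 1.96 * se)
  agg$pred <- predict_means(est)
  list(estimates = est, se = se, ci = ci, rss = fit$value,
       fitted = agg, convergence = fit$convergence)
}
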