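#' Kinetic parameters of one regulatory RNA array transcription unit
#'
#' Bundles the rate constants of the array model: an array transcript is
#' produced at rate `u`, cleaved by Csy4 at rate `k_c` releasing `eps * n`
#' free STAR molecules per transcript, and the free STAR pool activates a
#' target-RNA-controlled output gene with half-activation constant `K` and
#' off-state leak fraction `lam`.
#'
#' All concentrations and rates are in arbitrary units; the defaults are
#' estimates chosen to place the standard copy series (1--8 copies at
#' input 0.5) in the sub-saturating regime, not measured values.
#'
#' @param u transcription input rate of the array promoter (a.u./time).
#' @param k_c Csy4 cleavage rate of the array transcript (1/time).
#' @param d_A,d_S,d_G first-order degradation rates of the intact array
#'   transcript, free STAR, and output RNA (1/time); must be positive
#'   (`d_A` may be zero only together with a positive `k_c`).
#' @param eps cleavage/release efficiency per STAR copy, in `[0, 1]`.
#' @param n STAR copy number encoded on the array. Interfaces treat it as an
#'   integer in 0..8 but the arithmetic accepts any non-negative real (used
#'   by the copy/efficiency exchangeability identity).
#' @param a_T maximal transcription rate of the target-controlled output
#'   gene (a.u./time).
#' @param K free-STAR level giving half-maximal activation (a.u.).
#' @param lam leak fraction: share of target transcription events that fire
#'   with no STAR bound, in `[0, 1]`.
#'
#' @return An object of class `model_params` (a named list).
#' @examples
#' p <- model_params()
#' steady_state(p)
#' @seealso [steady_state()], [simulate_timecourse()]
#' @export
model_params <- function(u = 0.5, k_c = 1, d_A = 0.1, d_S = 1, d_G = 1,
                         eps = 0.9, n = 1, a_T = 1, K = 10, lam = 0.02) {
  p <- structure(
    list(u = u, k_c = k_c, d_A = d_A, d_S = d_S, d_G = d_G,
         eps = eps, n = n, a_T = a_T, K = K, lam = lam),
    class = "model_params")
  validate_model_params(p)
  p
}

#' Validate a set of model parameters
#'
#' Checks the parameter invariants (non-negative rates, positive
#' degradation, `eps` and `lam` in `[0, 1]`, `K > 0`) and signals an error
#' naming the first offending field.
#'
#' @param p a `model_params` object or a named list with the same fields.
#' @return `p`, invisibly, coerced to `model_params`.
#' @export
validate_model_params <- function(p) {
  fields <- c("u", "k_c", "d_A", "d_S", "d_G", "eps", "n", "a_T", "K", "lam")
  missing <- setdiff(fields, names(p))
  if (length(missing))
    stop("model parameters missing field(s): ", paste(missing, collapse = ", "))
  for (f in fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number")
  }
  chk <- function(ok, f, what) if (!ok) stop("invalid parameter '", f, "': ", what)
  chk(p$u >= 0, "u", "must be >= 0")
  chk(p$k_c >= 0, "k_c", "must be >= 0")
  chk(p$d_A >= 0, "d_A", "must be >= 0")
  chk(p$k_c + p$d_A > 0, "d_A", "k_c + d_A must be > 0")
  chk(p$d_S > 0, "d_S", "must be > 0")
  chk(p$d_G > 0, "d_G", "must be > 0")
  chk(p$eps >= 0 && p$eps <= 1, "eps", "must be in [0, 1]")
  chk(p$n >= 0, "n", "must be >= 0")
  chk(p$a_T >= 0, "a_T", "must be >= 0")
  chk(p$K > 0, "K", "must be > 0")
  chk(p$lam >= 0 && p$lam <= 1, "lam", "must be in [0, 1]")
  if (!inherits(p, "model_params")) class(p) <- "model_params"
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Regulatory RNA array model parameters:\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 4), " = ", format(v)), sep = "\n")
  invisible(x)
}

# Replace selected fields of a parameter set and re-validate.
#' Update model parameters
#'
#' Returns a copy of `p` with the named fields replaced, after validation.
#'
#' @param p a `model_params` object.
#' @param ... fields to replace, e.g. `with_params(p, n = 4, u = 0.2)`.
#' @return A `model_params` object.
#' @export
with_params <- function(p, ...) {
  upd <- list(...)
  bad <- setdiff(names(upd), names(p))
  if (length(bad)) stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
  p[names(upd)] <- upd
  validate_model_params(p)
  p
}
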