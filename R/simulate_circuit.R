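# Evaluation of circuits: closed-form chaining in topological order, and a
# joint ODE of all species as an independent route to the same fixed point.

# Transcription input of one unit given the resolved outputs so far.
unit_input <- function(u, condition, outputs) {
  base <- switch(u$driver$type,
    constant = u$driver$u,
    inducible = if (identical(condition, "on")) u$driver$u_on else u$driver$u_off,
    unit = outputs[[u$driver$ref]]$out_rate)
  u$mult * base
}

# STAR pool that activates this unit's target, from the resolved outputs.
unit_pool <- function(u, outputs, self_S) {
  if (identical(u$s_source, "none")) return(0)
  if (identical(u$s_source, "self")) {
    if (length(self_S) == 0) return(0)
    if (length(self_S) > 1)
      stop("unit '", u$id, "' encodes several variants; set s_source explicitly")
    return(unname(self_S))
  }
  src <- outputs[[u$s_source$unit]]$S_star
  if (!u$s_source$variant %in% names(src))
    stop("unit '", u$s_source$unit, "' releases no pool for variant '",
         u$s_source$variant, "'")
  unname(src[u$s_source$variant])
}

#' Steady-state evaluation of a circuit
#'
#' Resolves every transcription unit's closed-form steady state in
#' topological order: a unit's transcription input is its plasmid-copy
#' multiplier times either a constant/inducible level or the upstream unit's
#' activated target transcription rate
#' \eqn{a_T (\lambda + (1-\lambda)\theta)}; its target activation uses the
#' designated free-STAR pool. Agrees with joint ODE integration of all
#' species ([simulate_circuit_ode()]).
#'
#' @param circ a [circuit()].
#' @param condition `"on"` or `"off"`; selects the level of every inducible
#'   driver in the circuit (constant drivers are unaffected).
#' @return A `circuit_output` list: `reporters` (named steady-state levels of
#'   each reporter-tagged unit), `units` (per-unit steady-state detail), and
#'   the evaluated `condition`.
#' @export
simulate_circuit <- function(circ, condition = "on") {
  stopifnot(inherits(circ, "circuit"), condition %in% c("on", "off"))
  outputs <- list()
  for (id in circ$order) {
    un <- circ$units[[id]]
    p <- un$params
    u_in <- unit_input(un, condition, outputs)
    A <- u_in / (p$k_c + p$d_A)
    S <- if (nrow(un$blocks))
      stats::setNames(un$eps * un$blocks$copies * p$k_c * A / p$d_S,
                      un$blocks$variant)
    else stats::setNames(numeric(0), character(0))
    pool <- unit_pool(un, outputs, S)
    theta <- pool / (p$K + pool)
    act <- p$lam + (1 - p$lam) * theta
    outputs[[id]] <- list(u = u_in, A_star = A, S_star = S, theta = theta,
                          out_rate = p$a_T * act,
                          G_star = un$mult * p$a_T * act / p$d_G)
  }
  reporters <- list()
  for (id in circ$order) {
    rep_tag <- circ$units[[id]]$reporter
    if (rep_tag != "none") reporters[[rep_tag]] <- outputs[[id]]$G_star
  }
  structure(list(reporters = unlist(reporters), units = outputs,
                 condition = condition), class = "circuit_output")
}

#' @export
print.circuit_output <- function(x, ...) {
  cat("circuit steady state (condition:", x$condition, ")\n")
  for (id in names(x$units))
    cat(sprintf("  %s: u = %.4g, theta = %.4g, G* = %.4g\n",
                id, x$units[[id]]$u, x$units[[id]]$theta, x$units[[id]]$G_star))
  if (length(x$reporters))
    cat("reporters:", paste(names(x$reporters), "=",
                            signif(x$reporters, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Joint ODE integration of a whole circuit
#'
#' Stacks every unit's species (array transcript, one free-STAR pool per
#' encoded variant, output RNA) into one ODE system with instantaneous
#' inter-unit coupling and integrates it from zero initial conditions. Used
#' as the independent oracle for [simulate_circuit()].
#'
#' @inheritParams simulate_circuit
#' @param t_end integration end time; defaults to 40 slowest lifetimes.
#' @param n_out number of output times.
#' @return A list: `times`, `states` (matrix, one column per species, named
#'   `unit.A`, `unit.S.variant`, `unit.G`), `final` (last row).
#' @export
simulate_circuit_ode <- function(circ, condition = "on", t_end = NULL,
                                 n_out = 101) {
  stopifnot(inherits(circ, "circuit"), condition %in% c("on", "off"))
  units <- circ$units
  # index layout
  idx <- list(); nm <- character(0); pos <- 0L
  for (id in names(units)) {
    un <- units[[id]]
    iA <- pos + 1L
    iS <- if (nrow(un$blocks)) pos + 1L + seq_len(nrow(un$blocks)) else integer(0)
    iG <- pos + 2L + nrow(un$blocks)
    idx[[id]] <- list(A = iA, S = stats::setNames(iS, un$blocks$variant), G = iG)
    nm <- c(nm, paste0(id, ".A"),
            if (nrow(un$blocks)) paste0(id, ".S.", un$blocks$variant), paste0(id, ".G"))
    pos <- iG
  }
  if (is.null(t_end)) {
    rates <- unlist(lapply(units, function(u)
      c(u$params$d_A + u$params$k_c, u$params$d_S, u$params$d_G)))
    t_end <- 40 / min(rates[rates > 0])
  }
  rhs <- function(t, y) {
    dy <- numeric(length(y))
    theta_of <- function(id) {
      un <- units[[id]]
      pool <- if (identical(un$s_source, "none")) 0
      else if (identical(un$s_source, "self")) {
        if (length(idx[[id]]$S) == 1) y[idx[[id]]$S] else 0
      } else y[idx[[un$s_source$unit]]$S[un$s_source$variant]]
      pool / (un$params$K + pool)
    }
    for (id in names(units)) {
      un <- units[[id]]; p <- un$params; ix <- idx[[id]]
      base <- switch(un$driver$type,
        constant = un$driver$u,
        inducible = if (identical(condition, "on")) un$driver$u_on else un$driver$u_off,
        unit = {
          drv <- units[[un$driver$ref]]$params
          drv$a_T * (drv$lam + (1 - drv$lam) * theta_of(un$driver$ref))
        })
      u_in <- un$mult * base
      dy[ix$A] <- u_in - (p$k_c + p$d_A) * y[ix$A]
      if (length(ix$S))
        dy[ix$S] <- un$eps * un$blocks$copies * p$k_c * y[ix$A] - p$d_S * y[ix$S]
      act <- p$lam + (1 - p$lam) * theta_of(id)
      dy[ix$G] <- un$mult * p$a_T * act - p$d_G * y[ix$G]
    }
    dy
  }
  times <- seq(0, t_end, length.out = n_out)
  sol <- ode_integrate(rhs, numeric(pos), times)
  colnames(sol) <- nm
  list(times = times, states = sol, final = sol[nrow(sol), ])
}

#' Fold activation of a circuit's terminal reporter
#'
#' Evaluates the circuit in its on and off conditions and returns the ratio
#' of reporter steady states, `G_on / G_off`. The fold exceeds 1 whenever
#' the off state is leak-limited (`lam < 1`) and the on input is positive.
#'
#' @param circ a [circuit()] containing at least one inducible driver and
#'   one reporter-tagged unit.
#' @return Named numeric vector of folds, one per reporter (a single value
#'   for single-reporter circuits). A zero off state (`lam = 0`) raises a
#'   `starkit_infinite_fold` warning and yields `Inf` rather than failing
#'   silently.
#' @export
fold_activation_sim <- function(circ) {
  on <- simulate_circuit(circ, "on")$reporters
  off <- simulate_circuit(circ, "off")$reporters
  if (length(on) == 0) stop("circuit has no reporter-tagged unit")
  if (any(off == 0)) {
    warning(warningCondition(
      paste("off-state reporter level is exactly zero (lam = 0):",
            "fold activation is infinite"),
      class = "starkit_infinite_fold"))
  }
  fold <- on / off
  if (length(fold) == 1) unname(fold) else fold
}
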