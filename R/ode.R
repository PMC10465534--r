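# Adaptive explicit Runge-Kutta integrator (Dormand-Prince 5(4)).
#
# No general-purpose ODE solver ships with this package's dependency set,
# so a small embedded-pair integrator is implemented here. The array model
# and its circuit compositions are low-dimensional and non-stiff for valid
# parameters (all eigenvalues of the linear part are -d_*), so an explicit
# adaptive pair with tight tolerances is adequate; steady states are always
# taken from closed forms, never from integration heuristics.

# Butcher tableau of the Dormand-Prince 5(4) pair.
.dp45 <- local({
  a <- matrix(0, 7, 7)
  a[2, 1] <- 1 / 5
  a[3, 1:2] <- c(3 / 40, 9 / 40)
  a[4, 1:3] <- c(44 / 45, -56 / 15, 32 / 9)
  a[5, 1:4] <- c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729)
  a[6, 1:5] <- c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656)
  a[7, 1:6] <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
  b5 <- a[7, ]
  b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
          187 / 2100, 1 / 40)
  cc <- c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
  list(a = a, b5 = b5, b4 = b4, cc = cc)
})

# Integrate dy/dt = f(t, y) and return the solution at `times` (which must
# start at the initial time and be strictly increasing). Steps are capped so
# the solver lands exactly on every output time. Errors out on non-finite
# states with a diagnostic rather than returning garbage.
ode_integrate <- function(f, y0, times, atol = 1e-9, rtol = 1e-6,
                          h_init = NULL, max_steps = 5e5) {
  stopifnot(length(times) >= 2, all(diff(times) > 0))
  tab <- .dp45
  m <- length(y0)
  out <- matrix(NA_real_, length(times), m)
  out[1, ] <- y0
  t <- times[1]
  y <- y0
  k <- matrix(0, 7, m)
  k[1, ] <- f(t, y)
  h <- if (is.null(h_init)) (times[length(times)] - times[1]) / 100 else h_init
  next_i <- 2L
  steps <- 0L
  while (next_i <= length(times)) {
    if (steps >= max_steps)
      stop("integration failure: step limit reached at t = ", format(t))
    h <- min(h, times[next_i] - t)
    for (s in 2:7) {
      ys <- y + h * drop(tab$a[s, 1:(s - 1), drop = FALSE] %*% k[1:(s - 1), , drop = FALSE])
      k[s, ] <- f(t + tab$cc[s] * h, ys)
    }
    y5 <- y + h * drop(tab$b5 %*% k)
    y4 <- y + h * drop(tab$b4 %*% k)
    if (!all(is.finite(y5)))
      stop("integration failure: non-finite state at t = ", format(t),
           " (h = ", format(h), "); check parameter magnitudes")
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (err <= 1) {
      t <- t + h
      y <- y5
      k[1, ] <- k[7, ]  # FSAL property of the pair
      while (next_i <= length(times) && abs(t - times[next_i]) <= 1e-12 * max(1, abs(t))) {
        out[next_i, ] <- y
        next_i <- next_i + 1L
      }
    }
    fac <- if (err == 0) 5 else min(5, max(0.2, 0.9 * err^(-0.2)))
    h <- h * fac
    if (t + h == t) stop("integration failure: step underflow at t = ", format(t))
    steps <- steps + 1L
  }
  out
}
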