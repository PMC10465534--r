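test_that("steady state matches the closed form and its limiting cases", {
  # zero input: no STAR, leak-only output
  ss0 <- steady_state(default_params(u = 0, n = 5))
  expect_equal(ss0$S_star, 0)
  expect_equal(ss0$G_star, 0.02)
  # no cleavage release: leak only
  ss_e <- steady_state(default_params(eps = 0, u = 1))
  expect_equal(ss_e$theta, 0)
  expect_equal(ss_e$G_star, 0.02)
  # hand-computed closed form at the reference parameter point:
  # A* = 0.5/1.1, S* = 9/22, theta = 9/229, G* = 0.02 + 0.98 * 9/229
  ss <- steady_state(default_params())
  expect_equal(ss$A_star, 5 / 11)
  expect_equal(ss$S_star, 9 / 22)
  expect_equal(ss$theta, 9 / 229)
  expect_equal(ss$G_star, 0.0585152838427948, tolerance = 1e-12)
})

test_that("steady state is monotone in u, n, eps and bounded by a_T/d_G", {
  p <- default_params()
  g <- function(...) steady_state(with_params(p, ...))$G_star
  expect_true(g(u = 1) > g(u = 0.5))
  expect_true(g(n = 4) > g(n = 2))
  expect_true(g(eps = 0.9) > g(eps = 0.45))
  withr::with_seed(7, for (i in 1:50) {
    q <- rand_params()
    expect_lt(steady_state(q)$G_star, q$a_T / q$d_G)
  })
  # G* -> a_T/d_G as u -> infinity when lam < 1
  expect_equal(g(u = 1e9), 1, tolerance = 1e-5)
})

test_that("time course integrates to the closed-form fixed point", {
  p <- default_params()
  tr <- simulate_timecourse(p, t_end = 50 / 0.1)
  ss <- steady_state(p)
  expect_true(all(tr$A >= 0 & tr$S >= 0 & tr$G >= 0))
  expect_equal(tail(tr$G, 1), ss$G_star, tolerance = 1e-4)
  expect_equal(tail(tr$A, 1), ss$A_star, tolerance = 1e-4)
  # u = 0, zero initial: A,S identically 0 and G(t) relaxes as a known
  # linear closed form
  p0 <- default_params(u = 0)
  tr0 <- simulate_timecourse(p0, t_end = 5, n_out = 51)
  expect_equal(max(abs(tr0$A)), 0)
  expect_equal(max(abs(tr0$S)), 0)
  expect_equal(tr0$G, 0.02 * (1 - exp(-tr0$time)), tolerance = 1e-6)
  # doubling n doubles S when S << K (S is linear in n exactly)
  s1 <- tail(simulate_timecourse(default_params(n = 1), 80)$S, 1)
  s2 <- tail(simulate_timecourse(default_params(n = 2), 80)$S, 1)
  expect_equal(s2 / s1, 2, tolerance = 1e-6)
  expect_error(simulate_timecourse(p, t_end = -1), "t_end")
  expect_error(simulate_timecourse(p, 10, initial = c(-1, 0, 0)), "initial")
})

test_that("integrator agrees with the closed form on random parameter draws", {
  withr::with_seed(11, for (i in 1:100) {
    p <- rand_params()
    rates <- c(p$d_A + p$k_c, p$d_S, p$d_G)
    t_end <- 30 / min(rates)
    g_end <- tail(simulate_timecourse(p, t_end, n_out = 5)$G, 1)
    g_star <- steady_state(p)$G_star
    expect_lt(abs(g_end - g_star) / g_star, 1e-3)
  })
})

test_that("input-output curves are monotone, ordered in n, and saturate", {
  p <- default_params()
  u_grid <- seq(0, 4, by = 0.25)
  tab <- input_output_curve(p, u_grid, n_list = c(1, 2, 4, 6, 8))
  for (n in unique(tab$n)) {
    g <- tab$G_star[tab$n == n]
    expect_true(all(diff(g) >= 0))
    expect_true(all(g < p$a_T / p$d_G))
  }
  wide <- matrix(tab$G_star, nrow = length(u_grid))
  expect_true(all(diff(t(wide)) >= 0))  # larger n dominates pointwise
  # zero input: constant leak row
  z <- input_output_curve(p, 0, n_list = c(1, 4, 8))
  expect_equal(z$G_star, rep(0.02, 3))
  # higher cleavage efficiency dominates pointwise
  hi <- input_output_curve(with_params(p, eps = 0.9), u_grid, 4)$G_star
  lo <- input_output_curve(with_params(p, eps = 0.3), u_grid, 4)$G_star
  expect_true(all(hi >= lo))
  expect_error(input_output_curve(p, c(0.1, -0.2)), "u")
  expect_error(input_output_curve(p, numeric(0)), "non-empty")
})

test_that("gain_vs_copies matches per-point closed forms and the Pearson oracle", {
  p <- default_params()
  gt <- gain_vs_copies(p, copies = c(1, 2, 4, 6, 8), u = 0.5)
  expect_equal(gt$table$G_star,
               sapply(c(1, 2, 4, 6, 8), function(n) oracle_G(0.5, n)))
  expect_equal(gt$r, oracle_pearson(gt$table$n, gt$table$G_star), tolerance = 1e-12)
  # near-linear limit: K >> S* gives r ~ 1
  gt_lin <- gain_vs_copies(with_params(p, K = 1e9), u = 0.5)
  expect_equal(gt_lin$r, 1, tolerance = 1e-9)
  expect_error(gain_vs_copies(p, copies = c(1, 2)), "3 copy levels")
  expect_error(gain_vs_copies(p, copies = c(1, 1, 2)), "distinct")
})

test_that("lower eps lowers the slope but not the linearity; leak shifts curves", {
  # deep sub-saturation (S*(8) ~ 0.05 K); relative curvature of theta grows
  # quadratically in S/K, so the 1% linearity band needs this margin
  p <- default_params(u = 0.075)
  g_hi <- gain_vs_copies(with_params(p, eps = 0.9))
  g_lo <- gain_vs_copies(with_params(p, eps = 0.45))
  expect_lt(g_lo$slope, g_hi$slope)
  expect_gt(g_lo$r, 0.99)
  expect_gt(g_hi$r, 0.99)
  # linear regime: max relative deviation from the least-squares line < 1%
  fitted <- g_hi$intercept + g_hi$slope * g_hi$table$n
  expect_lt(max(abs(g_hi$table$G_star - fitted) / g_hi$table$G_star), 0.01)
  # leak shift identity: G*(lam) = (1 - lam) G*(0) + lam a_T/d_G, exactly
  for (lam in c(0, 0.05, 0.3, 0.9)) {
    g_lam <- steady_state(with_params(p, lam = lam, n = 4))$G_star
    g_0 <- steady_state(with_params(p, lam = 0, n = 4))$G_star
    expect_equal(g_lam, (1 - lam) * g_0 + lam * p$a_T / p$d_G, tolerance = 1e-15)
  }
  # fitted intercept increases with lam, slope scales by (1 - lam)
  g_leaky <- gain_vs_copies(with_params(p, lam = 0.2))
  g_tight <- gain_vs_copies(with_params(p, lam = 0.02))
  expect_gt(g_leaky$intercept, g_tight$intercept)
  g0 <- gain_vs_copies(with_params(p, lam = 0))
  expect_equal(g_leaky$slope, 0.8 * g0$slope, tolerance = 1e-12)
})

test_that("S* depends on eps * n only (copy/efficiency exchangeability)", {
  p <- default_params()
  a <- steady_state(with_params(p, eps = 0.5, n = 4))
  b <- steady_state(with_params(p, eps = 1, n = 2))
  expect_identical(a$S_star, b$S_star)
  expect_identical(a$G_star, b$G_star)
})

test_that("limiting 8x vs 1x leak-subtracted gain ratio is 8", {
  expect_equal(limiting_gain_ratio(default_params()), 8, tolerance = 1e-6)
  expect_equal(limiting_gain_ratio(default_params(), n_hi = 4, n_lo = 2), 2,
               tolerance = 1e-6)
  expect_error(limiting_gain_ratio(default_params(lam = 1)), "lam")
})
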