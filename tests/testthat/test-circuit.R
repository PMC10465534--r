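test_that("array_spec validates blocks and insulators", {
  a <- array_spec(c(STAR10 = 4))
  expect_equal(a$total_copies, 4)
  expect_equal(a$eps, 0.9)  # shcsy4hp catalogue value
  expect_error(array_spec(c(STAR10 = 0)), "copy counts")
  expect_error(array_spec(c(STAR10 = 1), insulator = "nope"), "insulator")
  expect_warning(array_spec(c(STAR10 = 9)), "exceeds")
})

test_that("a single-unit amplifier reproduces the core model exactly", {
  p <- default_params()
  for (n in c(1, 4, 8)) {
    amp <- build_amplifier(array_spec(stats::setNames(n, "STAR50")),
                           inducible_input = 0.5, params = p)
    expect_equal(simulate_circuit(amp)$reporters[["GFP"]],
                 steady_state(with_params(p, n = n, eps = 0.9))$G_star,
                 tolerance = 1e-14)
  }
  expect_error(build_amplifier(array_spec(c(STARX = 1)), 0.5),
               "unknown STAR variant")
})

test_that("leak-subtracted 8x/1x amplifier output ratio tends to 8 at low input", {
  p <- default_params()
  leak <- p$lam * p$a_T / p$d_G
  out <- function(n, u) {
    amp <- build_amplifier(array_spec(stats::setNames(n, "STAR50")), u, params = p)
    simulate_circuit(amp)$reporters[["GFP"]]
  }
  ratio <- (out(8, 1e-7) - leak) / (out(1, 1e-7) - leak)
  expect_equal(ratio, 8, tolerance = 1e-5)
})

test_that("PlmJ insulation yields little copy-number gain relative to shcsy4hp", {
  p <- default_params()
  raw_ratio <- function(ins) {
    o <- function(n) simulate_circuit(build_amplifier(
      array_spec(stats::setNames(n, "STAR50"), insulator = ins),
      0.5, params = p))$reporters[["GFP"]]
    o(4) / o(1)
  }
  expect_lt(raw_ratio("PlmJ"), raw_ratio("shcsy4hp"))
  expect_lt(raw_ratio("PlmJ"), 1.5)  # "little increase" from x4 vs x1
})

test_that("cascade on/off states order with array copies; folds match chained closed forms", {
  p <- default_params()
  x1 <- build_cascade(array = array_spec(c(STAR10 = 1)), params = p)
  x4 <- build_cascade(array = array_spec(c(STAR10 = 4)), params = p)
  on1 <- simulate_circuit(x1, "on")$reporters[["GFP"]]
  on4 <- simulate_circuit(x4, "on")$reporters[["GFP"]]
  off1 <- simulate_circuit(x1, "off")$reporters[["GFP"]]
  off4 <- simulate_circuit(x4, "off")$reporters[["GFP"]]
  expect_gt(on4, on1)     # on-state amplification
  expect_gt(off4, off1)   # the array amplifies the off state too
  # independent chained-closed-form oracle for the x4 fold
  chain <- function(u_in, n) {
    th1 <- function(u) { s <- 1 * 1 * (u / 1.1); s / (10 + s) }
    u1 <- 10 * u_in                         # stage-1 plasmid multiplier
    rate1 <- 1 * (0.02 + 0.98 * th1(u1))    # stage-1 activated target rate
    u2 <- 5 * rate1                         # array unit input
    s2 <- 0.9 * n * (u2 / 1.1)
    th2 <- s2 / (10 + s2)
    1 * 1 * (0.02 + 0.98 * th2) / 1         # reporter G*, mult 1
  }
  expect_equal(on4, chain(0.5, 4), tolerance = 1e-12)
  expect_equal(fold_activation_sim(x4), chain(0.5, 4) / chain(0, 4),
               tolerance = 1e-12)
  expect_equal(fold_activation_sim(x1), chain(0.5, 1) / chain(0, 1),
               tolerance = 1e-12)
  expect_error(build_cascade(stage1_variant = "STAR10",
                             array = array_spec(c(STAR10 = 1))), "orthogonal")
})

test_that("fold activation handles identity, full leak, and zero off state", {
  p <- default_params()
  same <- build_amplifier(array_spec(c(STAR50 = 2)),
                          list(u_on = 0.5, u_off = 0.5), params = p)
  expect_equal(fold_activation_sim(same), 1)
  leaky <- build_amplifier(array_spec(c(STAR50 = 2)),
                           list(u_on = 0.5, u_off = 0),
                           params = with_params(p, lam = 1 - 1e-12))
  expect_equal(fold_activation_sim(leaky), 1, tolerance = 1e-9)
  lam0 <- build_amplifier(array_spec(c(STAR50 = 2)),
                          list(u_on = 0.5, u_off = 0),
                          params = with_params(p, lam = 0))
  expect_warning(f <- fold_activation_sim(lam0), class = "starkit_infinite_fold")
  expect_identical(f, Inf)
  # fold > 1 whenever lam < 1 and the on input is positive
  active <- build_amplifier(array_spec(c(STAR50 = 2)),
                            list(u_on = 0.3, u_off = 0), params = p)
  expect_gt(fold_activation_sim(active), 1)
})

test_that("multiplex branches are independent and weighted by copies", {
  g <- function(n, m) simulate_circuit(build_multiplex(n, m))$reporters
  # perturbing m never changes GFP; perturbing n never changes RFP
  expect_identical(g(1, 1)[["GFP"]], g(1, 2)[["GFP"]])
  expect_identical(g(1, 1)[["RFP"]], g(2, 1)[["RFP"]])
  expect_lt(g(1, 2)[["GFP"]], g(2, 2)[["GFP"]])
  # weight matrix structure over {1,2} x {1,2}
  for (n in 1:2) for (m in 1:2) {
    expect_identical(g(n, m)[["GFP"]], g(n, 1)[["GFP"]])
    expect_identical(g(n, m)[["RFP"]], g(1, m)[["RFP"]])
  }
  # sub-saturating limit: GFP ratio of (2,1) to (1,1) -> 2
  leak <- 0.02
  lo <- simulate_circuit(build_multiplex(1, 1, input = 1e-7))$reporters
  hi <- simulate_circuit(build_multiplex(2, 1, input = 1e-7))$reporters
  expect_equal((hi[["GFP"]] - leak) / (lo[["GFP"]] - leak), 2, tolerance = 1e-5)
  expect_error(build_multiplex(0, 1), ">= 1")
})

test_that("circuit validation rejects cycles and dangling references", {
  p <- default_params()
  u1 <- starkit:::new_unit("a", p, driver = list(type = "unit", ref = "b"),
                           blocks = c(v = 1))
  u2 <- starkit:::new_unit("b", p, driver = list(type = "unit", ref = "a"),
                           blocks = c(v = 1))
  expect_error(circuit(list(u1, u2)), "cycle")
  u3 <- starkit:::new_unit("c", p, driver = list(type = "unit", ref = "ghost"),
                           blocks = c(v = 1))
  expect_error(circuit(list(u3)), "unresolvable")
  expect_error(starkit:::new_unit("d", p, driver = list(type = "constant", u = 0),
                                  mult = 0), "multiplier")
})

test_that("all-zero drivers with lam = 0 give identically zero outputs", {
  p <- default_params(lam = 0)
  circ <- build_cascade(array = array_spec(c(STAR10 = 4)),
                        input = list(u_on = 0, u_off = 0), params = p)
  out <- simulate_circuit(circ, "on")
  expect_true(all(vapply(out$units, `[[`, 0, "G_star") == 0))
})

test_that("topological evaluation agrees with joint ODE integration", {
  # 3-unit cascade, all 9 species integrated jointly
  casc <- build_cascade(array = array_spec(c(STAR10 = 4)))
  sol <- simulate_circuit_ode(casc, "on")
  closed <- simulate_circuit(casc, "on")
  expect_equal(unname(sol$final["reporter.G"]),
               closed$units$reporter$G_star, tolerance = 1e-3)
  # random acyclic chains
  withr::with_seed(23, for (i in 1:10) {
    circ <- rand_circuit()
    closed <- simulate_circuit(circ, "on")
    sol <- simulate_circuit_ode(circ, "on", n_out = 3)
    term <- paste0(circ$order[length(circ$order)], ".G")
    g <- closed$units[[circ$order[length(circ$order)]]]$G_star
    expect_lt(abs(sol$final[[term]] - g) / g, 1e-3)
  })
})
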