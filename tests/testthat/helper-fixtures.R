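# Shared fixtures and independent oracles.

default_params <- function(...) with_params(model_params(), ...)

# Independent closed-form oracle, written out as plain arithmetic (kept
# separate from the package's steady_state path on purpose).
oracle_G <- function(u, n, eps = 0.9, k_c = 1, d_A = 0.1, d_S = 1, d_G = 1,
                     a_T = 1, K = 10, lam = 0.02) {
  A <- u / (k_c + d_A)
  S <- eps * n * k_c * A / d_S
  (a_T / d_G) * (lam + (1 - lam) * S / (K + S))
}

# Brute-force Pearson correlation from the covariance definition.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Random valid parameter draws with rates kept in a well-conditioned band
# so integration windows stay short.
rand_params <- function() {
  model_params(u = runif(1, 0, 2), k_c = runif(1, 0.2, 2),
               d_A = runif(1, 0.05, 1), d_S = runif(1, 0.2, 2),
               d_G = runif(1, 0.2, 2), eps = runif(1, 0.1, 1),
               n = sample(1:8, 1), a_T = runif(1, 0.2, 2),
               K = runif(1, 1, 20), lam = runif(1, 0, 0.2))
}

# Random acyclic circuit of <= max_units units: a chain of driver-coupled
# units with random parameters (covers unit/constant drivers and reporters).
rand_circuit <- function(max_units = 5) {
  k <- sample(2:max_units, 1)
  units <- list()
  for (i in seq_len(k)) {
    p <- rand_params()
    drv <- if (i == 1) list(type = "constant", u = runif(1, 0.1, 1))
           else list(type = "unit", ref = paste0("u", i - 1))
    units[[i]] <- starkit:::new_unit(
      paste0("u", i), p, driver = drv,
      blocks = stats::setNames(p$n, paste0("v", i)),
      eps = p$eps, mult = runif(1, 0.5, 3),
      reporter = if (i == k) "GFP" else "none")
  }
  circuit(units)
}

# Minimal hand-built plate: one media blank, one blank-cells, samples.
tiny_plate <- function(sample_fl = 1100, sample_od = 0.54,
                       blank_fl = 100, blank_od = 0.04,
                       cells_fl = 140, cells_od = 0.24) {
  data.frame(
    well = c("B1", "B2", "S1"),
    role = c("media_blank", "blank_cells", "sample"),
    replicate = 1L,
    OD600 = c(blank_od, cells_od, sample_od),
    FL_GFP = c(blank_fl, cells_fl, sample_fl))
}

# Synthetic DNA parts honouring the AATG/GCTT overhang convention.
make_star <- function(id = "STARX", core = strrep("ACGTG", 12))
  dna_part(id, "STAR", paste0("AATG", core, "GCTT"))
make_insulator <- function(id = "INS", core = strrep("CTGA", 7))
  dna_part(id, "insulator", paste0("GCTT", core, "AATG"))

# Quadratic brute-force longest repeated substring (positions 0-based).
oracle_longest_repeat <- function(seq) {
  n <- nchar(seq)
  best <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    l <- 0L
    while (i + l <= n && j + l <= n &&
           substr(seq, i + l, i + l) == substr(seq, j + l, j + l))
      l <- l + 1L
    if (l > best) best <- l
  }
  best
}
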