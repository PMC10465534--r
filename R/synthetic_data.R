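# Synthetic plate-reader datasets with the statistical structure the
# analysis pipeline assumes: model-derived means, lognormal biological
# replicate noise, additive Gaussian read noise, media blanks and
# autofluorescent blank cells.

#' Noise and calibration model for synthetic plates
#'
#' Measurement model for one well: the true expression level in FL/OD units
#' is `gain * G_star`, multiplied per biological replicate by a lognormal
#' factor with unit mean and coefficient of variation `cv_bio`; the well's
#' OD above the media baseline is lognormal with mean `od_mean` and CV
#' `od_cv`; raw fluorescence is
#' `(expression + autofl) * OD_above_blank + blank_fl` plus additive
#' Gaussian read noise of SD `sd_read`; raw OD is the OD above blank plus
#' the media baseline `blank_od`. With all noise terms zero the pipeline
#' ([correct_plate()]) recovers `gain * G_star` exactly.
#'
#' @param cv_bio biological (between-replicate) lognormal CV.
#' @param sd_read additive Gaussian read noise on raw FL (raw FL units).
#' @param od_mean,od_cv mean and lognormal CV of sample OD above blank.
#' @param autofl autofluorescence of cells (FL/OD units).
#' @param gain calibration from model output (a.u.) to FL/OD units.
#' @param blank_od,blank_fl media-blank baselines (raw units).
#' @param seed integer seed; identical seeds give identical datasets.
#' @return A `noise_model` object.
#' @export
noise_model <- function(cv_bio = 0.1, sd_read = 20, od_mean = 0.5,
                        od_cv = 0.05, autofl = 200, gain = 1e4,
                        blank_od = 0.04, blank_fl = 100, seed = 1L) {
  stopifnot(cv_bio >= 0, sd_read >= 0, od_mean > 0, od_cv >= 0,
            autofl >= 0, gain > 0, length(seed) == 1)
  structure(list(cv_bio = cv_bio, sd_read = sd_read, od_mean = od_mean,
                 od_cv = od_cv, autofl = autofl, gain = gain,
                 blank_od = blank_od, blank_fl = blank_fl,
                 seed = as.integer(seed)), class = "noise_model")
}

# Lognormal factors with mean exactly 1 and coefficient of variation cv.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Experimental design of a synthetic plate
#'
#' Copy-number series, inducer dose series and replication mirroring the
#' characterisation experiments: copies drawn from \{1, 2, 4, 6, 8\}, doses
#' of 0.01/0.03/0.1/0.3 % arabinose (pBAD) or 10/30/60/100 uM cumate
#' (pCymR), and n = 4 biological replicates per condition.
#'
#' Doses are mapped to model transcription inputs through a ground-truth
#' Hill response (`basal + (1 - basal) * c^h / (c50^h + c^h)`), normalised
#' so that full induction equals `u_ref` — by default the reference input
#' 0.5 at which copy-number gain is read out.
#'
#' @param copies copy-number levels.
#' @param promoter `"pBAD"` or `"pCymR"`; sets the dose series and the Hill
#'   ground truth (`c50` = 0.06 % arabinose or 40 uM cumate, `h` = 1.5,
#'   `basal` = 0.02).
#' @param replicates biological replicates per condition (>= 2).
#' @param u_ref model transcription input at full induction.
#' @param n_blanks media-blank and blank-cell wells each.
#' @return An `experiment_design` object; its `doses` field tabulates the
#'   dose -> promoter-activity (`u`) ground truth.
#' @export
experiment_design <- function(copies = c(1, 2, 4, 6, 8), promoter = "pBAD",
                              replicates = 4, u_ref = 0.5, n_blanks = 4) {
  promoter <- match.arg(promoter, c("pBAD", "pCymR"))
  if (length(copies) == 0) stop("copies must be non-empty")
  if (replicates < 2) stop("replicates must be >= 2")
  dose <- switch(promoter, pBAD = c(0.01, 0.03, 0.1, 0.3),
                 pCymR = c(10, 30, 60, 100))
  c50 <- switch(promoter, pBAD = 0.06, pCymR = 40)
  h <- 1.5; basal <- 0.02
  act <- basal + (1 - basal) * dose^h / (c50^h + dose^h)
  u <- u_ref * act / act[length(act)]
  structure(list(copies = copies, promoter = promoter,
                 replicates = as.integer(replicates), u_ref = u_ref,
                 n_blanks = as.integer(n_blanks),
                 doses = data.frame(inducer = dose, activity = act, u = u)),
            class = "experiment_design")
}

# Render one block of wells as tidy rows.
well_rows <- function(prefix, k, role, construct = NA, copies = NA,
                      inducer = NA, u = NA) {
  data.frame(well = sprintf("%s%02d", prefix, seq_len(k)), role = role,
             construct = construct, copies = copies, inducer = inducer,
             u = u, replicate = seq_len(k))
}

# Turn a table of conditions (with true expression columns E_GFP / E_RFP)
# into raw measurements under the noise model. Deterministic under the seed.
measure_wells <- function(cond, noise) {
  n <- nrow(cond)
  od_above <- ifelse(cond$role == "media_blank", 0,
                     noise$od_mean * rlnorm_cv(n, noise$od_cv))
  out <- cond
  out$OD600 <- noise$blank_od + od_above
  for (ch in c("GFP", "RFP")) {
    e_col <- paste0("E_", ch)
    expr <- ifelse(cond$role == "media_blank", 0,
                   cond[[e_col]] * rlnorm_cv(n, noise$cv_bio) + noise$autofl)
    out[[paste0("FL_", ch)]] <- noise$blank_fl + expr * od_above +
      stats::rnorm(n, 0, noise$sd_read)
  }
  out$E_GFP <- NULL; out$E_RFP <- NULL
  out
}

#' Generate a synthetic plate dataset
#'
#' Builds a tidy plate (see [validate_plate()]) whose sample means derive
#' from the model: for a [model_params()] object, one condition per
#' (copy level x dose) of the design with GFP expression
#' `gain * G_star(u = dose input, n = copies)`; for a [circuit()], one
#' condition per on/off state with one expression column per reporter.
#' Media blanks and autofluorescent blank cells are included. Generation is
#' deterministic under `noise$seed`.
#'
#' @param design an [experiment_design()].
#' @param params a [model_params()] object or a [circuit()].
#' @param noise a [noise_model()].
#' @return A plate data frame with condition columns `construct`, `copies`,
#'   `inducer`, `u` (ground-truth promoter activity in model units) and a
#'   `truth` attribute recording the generating conditions.
#' @export
generate_plate <- function(design, params, noise = noise_model()) {
  stopifnot(inherits(design, "experiment_design"), inherits(noise, "noise_model"))
  reps <- design$replicates
  blanks <- rbind(well_rows("MB", design$n_blanks, "media_blank"),
                  well_rows("BC", design$n_blanks, "blank_cells"))
  blanks$E_GFP <- 0; blanks$E_RFP <- 0
  if (inherits(params, "model_params")) {
    grid <- expand.grid(copies = design$copies, dose_i = seq_len(nrow(design$doses)),
                        KEEP.OUT.ATTRS = FALSE)
    grid$inducer <- design$doses$inducer[grid$dose_i]
    grid$u <- design$doses$u[grid$dose_i]
    grid$G_star <- mapply(function(n, u)
      steady_state(with_params(params, n = n, u = u))$G_star, grid$copies, grid$u)
    rows <- grid[rep(seq_len(nrow(grid)), each = reps), ]
    rows$replicate <- rep(seq_len(reps), nrow(grid))
    samples <- data.frame(
      well = sprintf("S%03d", seq_len(nrow(rows))), role = "sample",
      construct = "array", copies = rows$copies, inducer = rows$inducer,
      u = rows$u, replicate = rows$replicate,
      E_GFP = noise$gain * rows$G_star, E_RFP = 0)
    truth_cond <- grid[, c("copies", "inducer", "u", "G_star")]
  } else if (inherits(params, "circuit")) {
    states <- c("on", "off")
    res <- lapply(states, function(s) simulate_circuit(params, s)$reporters)
    rows <- NULL
    for (i in seq_along(states)) {
      rep_lv <- res[[i]]
      rows <- rbind(rows, data.frame(
        condition = states[i], replicate = seq_len(reps),
        E_GFP = if ("GFP" %in% names(rep_lv)) noise$gain * rep_lv[["GFP"]] else 0,
        E_RFP = if ("RFP" %in% names(rep_lv)) noise$gain * rep_lv[["RFP"]] else 0))
    }
    samples <- data.frame(
      well = sprintf("S%03d", seq_len(nrow(rows))), role = "sample",
      construct = "circuit", copies = NA, inducer = NA, u = NA,
      condition = rows$condition, replicate = rows$replicate,
      E_GFP = rows$E_GFP, E_RFP = rows$E_RFP)
    blanks$condition <- NA
    truth_cond <- unique(rows[, c("condition", "E_GFP", "E_RFP")])
  } else stop("params must be a model_params object or a circuit")
  cond <- rbind(blanks[, names(samples)], samples)
  plate <- withr::with_seed(noise$seed, measure_wells(cond, noise))
  attr(plate, "truth") <- list(design = design, noise = noise,
                               conditions = truth_cond)
  validate_plate(plate)
  plate
}

#' Generate a copy-sweep characterisation plate
#'
#' Emulates a copy-number characterisation experiment: an inducible RNA
#' array at each (copy level x dose) with 4 biological replicates, plus
#' standard-curve wells of the corresponding inducible-GFP control
#' (expression `gain * (a_T / d_G) * u`), media blanks and blank cells.
#' On the generated data, [correct_plate()] followed by
#' [copy_correlation()] at the fully induced dose recovers the model's
#' linear copy-to-output relation (noise-free r > 0.999; r >= ~0.95 at the
#' default noise level).
#'
#' @inheritParams generate_plate
#' @return A plate data frame; control wells carry `construct = "control"`.
#' @export
generate_copy_sweep <- function(design = experiment_design(),
                                params = model_params(),
                                noise = noise_model()) {
  stopifnot(inherits(params, "model_params"))
  reps <- design$replicates
  blanks <- rbind(well_rows("MB", design$n_blanks, "media_blank"),
                  well_rows("BC", design$n_blanks, "blank_cells"))
  blanks$construct <- NA; blanks$E_GFP <- 0; blanks$E_RFP <- 0
  grid <- expand.grid(copies = design$copies, dose_i = seq_len(nrow(design$doses)),
                      KEEP.OUT.ATTRS = FALSE)
  grid$inducer <- design$doses$inducer[grid$dose_i]
  grid$u <- design$doses$u[grid$dose_i]
  grid$G_star <- mapply(function(n, u)
    steady_state(with_params(params, n = n, u = u))$G_star, grid$copies, grid$u)
  rows <- grid[rep(seq_len(nrow(grid)), each = reps), ]
  rows$replicate <- rep(seq_len(reps), nrow(grid))
  arrays <- data.frame(
    well = sprintf("S%03d", seq_len(nrow(rows))), role = "sample",
    construct = "array", copies = rows$copies, inducer = rows$inducer,
    u = rows$u, replicate = rows$replicate,
    E_GFP = noise$gain * rows$G_star, E_RFP = 0)
  ctrl_rows <- design$doses[rep(seq_len(nrow(design$doses)), each = reps), ]
  ctrl <- data.frame(
    well = sprintf("C%03d", seq_len(nrow(ctrl_rows))), role = "sample",
    construct = "control", copies = NA, inducer = ctrl_rows$inducer,
    u = ctrl_rows$u, replicate = rep(seq_len(reps), nrow(design$doses)),
    E_GFP = noise$gain * (params$a_T / params$d_G) * ctrl_rows$u, E_RFP = 0)
  cond <- rbind(blanks[, names(arrays)], arrays, ctrl)
  plate <- withr::with_seed(noise$seed, measure_wells(cond, noise))
  attr(plate, "truth") <- list(design = design, noise = noise, params = params,
                               conditions = grid[, c("copies", "inducer", "u", "G_star")])
  validate_plate(plate)
  plate
}

#' Copy-number correlation on a corrected copy-sweep plate
#'
#' Convenience wrapper: selects the array wells of one dose level (by
#' default the fully induced dose, the level at which the copy series is
#' read out), and runs [copy_correlation()] on the replicate-level
#' `(copies, FL/OD)` points.
#'
#' @param corrected a [correct_plate()]-corrected copy-sweep plate.
#' @param inducer dose level to analyse; default the maximum present.
#' @param channel fluorescence channel.
#' @return See [copy_correlation()].
#' @export
copy_sweep_correlation <- function(corrected, inducer = NULL,
                                   channel = "FL_GFP") {
  col <- paste0(channel, "_per_OD_corr")
  sel <- corrected$role == "sample" & corrected$construct == "array"
  if (is.null(inducer)) inducer <- max(corrected$inducer[sel], na.rm = TRUE)
  sel <- sel & corrected$inducer == inducer
  copy_correlation(corrected$copies[sel], corrected[[col]][sel])
}
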