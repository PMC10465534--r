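# Circuit composition of array transcription units.
#
# A transcription unit owns an (optional) RNA array transcript that releases
# one free-STAR pool per variant it encodes, plus one target-RNA-controlled
# output gene. Units are coupled through two kinds of directed edges:
#   * u-driver: the unit's transcription input u is the activated
#     transcription rate of an upstream unit's target promoter
#     (a_T * (lam + (1 - lam) * theta)), scaled by this unit's plasmid
#     copy-number multiplier; or a constant / inducible level.
#   * s-source: the STAR pool that activates the unit's target; by default
#     the unit's own (single-variant) pool, but a reporter-only unit can be
#     activated by a pool released from another unit's array (multiplexing).

# Default per-insulator release efficiencies. The strong-hairpin Csy4 design
# folds robustly; the bare Csy4 hairpin partially misfolds; the hammerhead
# ribozyme insulates tandem STARs poorly. Estimates, editable per ArraySpec.
insulator_eps_defaults <- c(shcsy4hp = 0.90, csy4hp = 0.75, PlmJ = 0.05)

#' Specification of one regulatory RNA array transcript
#'
#' Describes the composition of an array: an ordered set of STAR-variant
#' blocks (variant id + copy count) and the cleavable insulator that
#' separates the copies, which determines the per-copy release efficiency.
#'
#' @param blocks a data frame with columns `variant` (character) and
#'   `copies` (integer >= 1), or a named integer vector
#'   (e.g. `c(STAR10 = 4)`).
#' @param insulator one of `"shcsy4hp"`, `"csy4hp"`, `"PlmJ"`.
#' @param eps release efficiency per copy; defaults to the insulator's
#'   catalogue value.
#' @return An `array_spec` object.
#' @examples
#' array_spec(c(STAR10 = 2, STAR50 = 1))
#' @export
array_spec <- function(blocks, insulator = "shcsy4hp", eps = NULL) {
  if (is.numeric(blocks) && !is.null(names(blocks)))
    blocks <- data.frame(variant = names(blocks), copies = as.integer(blocks))
  if (!is.data.frame(blocks) || !all(c("variant", "copies") %in% names(blocks)))
    stop("blocks must be a data frame with columns 'variant' and 'copies'")
  if (any(blocks$copies < 1) || any(blocks$copies != round(blocks$copies)))
    stop("copy counts must be integers >= 1")
  if (!insulator %in% names(insulator_eps_defaults))
    stop("unknown insulator '", insulator, "'; known: ",
         paste(names(insulator_eps_defaults), collapse = ", "))
  if (is.null(eps)) eps <- unname(insulator_eps_defaults[insulator])
  if (eps < 0 || eps > 1) stop("eps must be in [0, 1]")
  total <- sum(blocks$copies)
  if (total > 8)
    warning("total copies = ", total, " exceeds the characterised range (<= 8)")
  structure(list(blocks = blocks, insulator = insulator, eps = eps,
                 total_copies = total), class = "array_spec")
}

# Internal constructor for one transcription unit of a circuit.
new_unit <- function(id, params, driver, blocks = NULL, eps = params$eps,
                     mult = 1, s_source = "self", reporter = "none") {
  params <- validate_model_params(params)
  if (!is.null(blocks)) {
    if (is.numeric(blocks) && !is.null(names(blocks)))
      blocks <- data.frame(variant = names(blocks), copies = as.integer(blocks))
  } else {
    blocks <- data.frame(variant = character(), copies = integer())
  }
  if (!mult > 0) stop("plasmid copy-number multiplier must be > 0")
  if (!reporter %in% c("GFP", "RFP", "none")) stop("unknown reporter tag")
  stopifnot(is.list(driver), driver$type %in% c("constant", "inducible", "unit"))
  list(id = id, params = params, driver = driver, blocks = blocks,
       eps = eps, mult = mult, s_source = s_source, reporter = reporter)
}

# Edges of the driver/source graph: from -> to (dependency -> dependent).
circuit_edges <- function(units) {
  edges <- NULL
  for (u in units) {
    if (identical(u$driver$type, "unit"))
      edges <- rbind(edges, c(u$driver$ref, u$id))
    if (is.list(u$s_source))
      edges <- rbind(edges, c(u$s_source$unit, u$id))
  }
  edges
}

# Kahn topological sort; errors on cycles or dangling references.
topo_order <- function(units) {
  ids <- vapply(units, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate unit ids in circuit")
  edges <- circuit_edges(units)
  if (!is.null(edges)) {
    missing <- setdiff(edges[, 1], ids)
    if (length(missing))
      stop("unresolvable driver/source reference(s): ", paste(missing, collapse = ", "))
  }
  indeg <- stats::setNames(integer(length(ids)), ids)
  if (!is.null(edges)) for (i in seq_len(nrow(edges)))
    indeg[edges[i, 2]] <- indeg[edges[i, 2]] + 1L
  order <- character(0)
  ready <- ids[indeg == 0]
  while (length(ready)) {
    v <- ready[1]; ready <- ready[-1]
    order <- c(order, v)
    if (!is.null(edges)) for (i in seq_len(nrow(edges))) {
      if (edges[i, 1] == v) {
        w <- edges[i, 2]
        indeg[w] <- indeg[w] - 1L
        if (indeg[w] == 0L) ready <- c(ready, w)
      }
    }
  }
  if (length(order) != length(ids)) stop("driver graph contains a cycle")
  order
}

#' Construct a circuit from transcription units
#'
#' Validates that unit ids are unique, every driver / STAR-pool reference
#' resolves, multipliers are positive, and the coupling graph is acyclic.
#'
#' @param units a list of units created by the `build_*` helpers (or
#'   internally via `new_unit`).
#' @return A `circuit` object (list with fields `units`, `order`).
#' @seealso [build_amplifier()], [build_cascade()], [build_multiplex()],
#'   [simulate_circuit()]
#' @export
circuit <- function(units) {
  order <- topo_order(units)
  names(units) <- vapply(units, `[[`, "", "id")
  structure(list(units = units, order = order), class = "circuit")
}

#' @export
print.circuit <- function(x, ...) {
  cat("circuit with", length(x$units), "transcription unit(s):\n")
  for (id in x$order) {
    u <- x$units[[id]]
    drv <- switch(u$driver$type,
                  constant = sprintf("u = %g", u$driver$u),
                  inducible = sprintf("u_on = %g / u_off = %g", u$driver$u_on, u$driver$u_off),
                  unit = paste0("<- ", u$driver$ref))
    blk <- if (nrow(u$blocks)) paste(u$blocks$variant, "x", u$blocks$copies, collapse = " + ")
           else "(no array)"
    cat(sprintf("  %s: %s; driver %s; mult %g; reporter %s\n",
                id, blk, drv, u$mult, u$reporter))
  }
  invisible(x)
}

#' Build a single-stage inducible array amplifier
#'
#' One transcription unit carrying the array; its steady state equals the
#' core model's with `n = ` total copies and `eps` from the insulator.
#'
#' @param array an [array_spec()] with a single STAR variant.
#' @param inducible_input either a single number (constant input) or a list
#'   `list(u_on =, u_off =)` defining on/off conditions.
#' @param params base [model_params()] for the unit.
#' @param reporter reporter tag of the unit's target gene.
#' @param mult plasmid copy-number multiplier.
#' @param known_variants STAR variant ids accepted by the part catalogue.
#' @return A `circuit` with one unit.
#' @examples
#' amp <- build_amplifier(array_spec(c(STAR50 = 4)), inducible_input = 0.5)
#' simulate_circuit(amp)
#' @export
build_amplifier <- function(array, inducible_input = list(u_on = 0.5, u_off = 0),
                            params = model_params(), reporter = "GFP", mult = 1,
                            known_variants = c("STAR10", "STAR50")) {
  stopifnot(inherits(array, "array_spec"))
  unknown <- setdiff(array$blocks$variant, known_variants)
  if (length(unknown))
    stop("unknown STAR variant id(s): ", paste(unknown, collapse = ", "))
  if (nrow(array$blocks) != 1)
    stop("an amplifier carries a single STAR variant; use build_multiplex for mixed arrays")
  driver <- if (is.numeric(inducible_input))
    list(type = "constant", u = inducible_input)
  else list(type = "inducible", u_on = inducible_input$u_on,
            u_off = inducible_input$u_off)
  u <- new_unit("amplifier",
                with_params(params, n = array$total_copies, eps = array$eps),
                driver = driver, blocks = array$blocks, eps = array$eps,
                mult = mult, reporter = reporter)
  circuit(list(u))
}

#' Build an activation-activation cascade with an array amplifier stage
#'
#' Stage 1 expresses one STAR variant from an inducible input; its activated
#' target promoter transcribes the intermediate RNA array (the amplifier
#' stage), whose released STAR pool activates the terminal reporter. The
#' three units sit on plasmids of decreasing copy number (defaults 10/5/1).
#'
#' @param stage1_variant STAR variant of the first stage (default STAR50).
#' @param array an [array_spec()] for the intermediate array; its variant
#'   must be orthogonal to (different from) `stage1_variant`.
#' @param reporter terminal reporter tag.
#' @param input list `list(u_on =, u_off =)` for the stage-1 inducible driver.
#' @param params base [model_params()] shared by all units.
#' @param plasmid_copies multipliers for the three plasmids, high to low.
#' @return A three-unit `circuit`.
#' @examples
#' casc <- build_cascade(array = array_spec(c(STAR10 = 4)))
#' fold_activation_sim(casc)
#' @export
build_cascade <- function(stage1_variant = "STAR50",
                          array = array_spec(c(STAR10 = 1)),
                          reporter = "GFP",
                          input = list(u_on = 0.5, u_off = 0),
                          params = model_params(),
                          plasmid_copies = c(10, 5, 1)) {
  stopifnot(inherits(array, "array_spec"), length(plasmid_copies) == 3)
  array_variant <- array$blocks$variant
  if (nrow(array$blocks) != 1)
    stop("the cascade's intermediate array carries a single STAR variant")
  if (identical(array_variant, stage1_variant))
    stop("array variant must be orthogonal to the stage-1 variant")
  u1 <- new_unit("stage1", with_params(params, n = 1, eps = 1),
                 driver = list(type = "inducible", u_on = input$u_on,
                               u_off = input$u_off),
                 blocks = stats::setNames(1L, stage1_variant), eps = 1,
                 mult = plasmid_copies[1])
  u2 <- new_unit("array",
                 with_params(params, n = array$total_copies, eps = array$eps),
                 driver = list(type = "unit", ref = "stage1"),
                 blocks = array$blocks, eps = array$eps,
                 mult = plasmid_copies[2])
  u3 <- new_unit("reporter", params,
                 driver = list(type = "constant", u = 0),
                 s_source = list(unit = "array", variant = array_variant),
                 mult = plasmid_copies[3], reporter = reporter)
  circuit(list(u1, u2, u3))
}

#' Build a 1-to-2 multiplex motif
#'
#' A single array transcript encodes `n` copies of STAR10 and `m` copies of
#' STAR50; the released STAR10 pool activates a GFP target and the STAR50
#' pool an RFP target. The two branches share the transcript but are
#' otherwise uncoupled, so GFP depends on `n` only and RFP on `m` only.
#'
#' @param n,m copy numbers of STAR10 (GFP branch) and STAR50 (RFP branch).
#' @param input constant or `list(u_on =, u_off =)` inducible array input.
#' @param params base [model_params()] shared by the units.
#' @param insulator insulator id for the mixed array.
#' @return A three-unit `circuit` with GFP and RFP reporters.
#' @examples
#' mx <- build_multiplex(2, 1)
#' simulate_circuit(mx)$reporters
#' @export
build_multiplex <- function(n, m, input = 0.5, params = model_params(),
                            insulator = "shcsy4hp") {
  if (n < 1 || m < 1) stop("n and m must be >= 1")
  arr <- array_spec(data.frame(variant = c("STAR10", "STAR50"),
                               copies = as.integer(c(n, m))),
                    insulator = insulator)
  driver <- if (is.numeric(input)) list(type = "constant", u = input)
            else list(type = "inducible", u_on = input$u_on, u_off = input$u_off)
  ua <- new_unit("array", with_params(params, eps = arr$eps),
                 driver = driver, blocks = arr$blocks, eps = arr$eps,
                 s_source = "none")
  ug <- new_unit("gfp", params, driver = list(type = "constant", u = 0),
                 s_source = list(unit = "array", variant = "STAR10"),
                 reporter = "GFP")
  ur <- new_unit("rfp", params, driver = list(type = "constant", u = 0),
                 s_source = list(unit = "array", variant = "STAR50"),
                 reporter = "RFP")
  circuit(list(ua, ug, ur))
}
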