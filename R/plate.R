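# Plate-reader measurement pipeline: blank correction, FL/OD,
# autofluorescence subtraction, fold activation.

plate_channels <- c("FL_GFP", "FL_RFP")

#' Validate a tidy plate-reader dataset
#'
#' A plate is a tidy data frame with one row per well and columns `well`,
#' `role` (one of `media_blank`, `blank_cells`, `sample`), `replicate`,
#' `OD600`, and the fluorescence channels `FL_GFP` / `FL_RFP` (GFP read at
#' 485/520 nm, RFP at 560/630 nm). Any further columns (`copies`,
#' `inducer`, `condition`, `species`, ...) are treated as condition labels.
#'
#' @param plate a data frame as described above.
#' @return `plate`, invisibly, if valid; otherwise an error.
#' @export
validate_plate <- function(plate) {
  need <- c("well", "role", "replicate", "OD600")
  missing <- setdiff(need, names(plate))
  if (length(missing))
    stop("plate is missing column(s): ", paste(missing, collapse = ", "))
  chans <- intersect(plate_channels, names(plate))
  if (!length(chans)) stop("plate has no fluorescence channel (FL_GFP / FL_RFP)")
  bad_role <- setdiff(unique(plate$role), c("media_blank", "blank_cells", "sample"))
  if (length(bad_role)) stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  for (r in c("media_blank", "blank_cells"))
    if (!any(plate$role == r)) stop("plate has no '", r, "' control wells")
  num <- plate[, c("OD600", chans)]
  if (!all(vapply(num, is.numeric, logical(1))) || any(!is.finite(as.matrix(num))))
    stop("raw OD600 / FL values must all be finite numbers")
  invisible(plate)
}

#' Blank-correct a plate and compute autofluorescence-subtracted FL/OD
#'
#' Applies the standard three-step arithmetic, in this fixed order:
#' \enumerate{
#'   \item subtract the media-blank mean from every well's OD and FL;
#'   \item divide corrected FL by corrected OD per well (FL/OD);
#'   \item subtract the mean FL/OD of the blank (autofluorescent) cells.
#' }
#' Wells whose corrected OD does not exceed `od_floor` get `NA` ratios, are
#' flagged, and a warning is raised; negative autofluorescence-subtracted
#' values are retained (not clipped) so replicate statistics stay unbiased.
#'
#' @param plate a tidy plate data frame (see [validate_plate()]).
#' @param od_floor minimum corrected OD for a valid FL/OD ratio.
#' @return The plate with added columns `OD_corr`, `<ch>_corr`,
#'   `<ch>_per_OD` (step 2), `<ch>_per_OD_corr` (step 3) for each channel,
#'   and a logical `flagged` column.
#' @examples
#' plate <- data.frame(
#'   well = c("A1", "A2", "A3"), role = c("media_blank", "blank_cells", "sample"),
#'   replicate = 1, OD600 = c(0.04, 0.54, 0.54), FL_GFP = c(100, 200, 1100))
#' correct_plate(plate)[3, "FL_GFP_per_OD_corr"]  # (1000/0.5) - (100/0.5) = 1800
#' @export
correct_plate <- function(plate, od_floor = 0.01) {
  validate_plate(plate)
  chans <- intersect(plate_channels, names(plate))
  mb <- plate$role == "media_blank"
  out <- plate
  out$OD_corr <- plate$OD600 - mean(plate$OD600[mb])
  for (ch in chans) out[[paste0(ch, "_corr")]] <- plate[[ch]] - mean(plate[[ch]][mb])
  out$flagged <- out$OD_corr <= od_floor & plate$role != "media_blank"
  ok <- out$OD_corr > od_floor
  for (ch in chans) {
    ratio <- ifelse(ok, out[[paste0(ch, "_corr")]] / out$OD_corr, NA_real_)
    out[[paste0(ch, "_per_OD")]] <- ratio
    auto <- mean(ratio[plate$role == "blank_cells"])
    if (!is.finite(auto))
      stop("blank-cells FL/OD undefined (corrected OD at or below od_floor)")
    out[[paste0(ch, "_per_OD_corr")]] <- ratio - auto
  }
  if (any(out$flagged))
    warning(sum(out$flagged), " well(s) at or below the corrected-OD floor (",
            od_floor, ") were flagged and their FL/OD set to NA")
  class(out) <- c("corrected_plate", "data.frame")
  out
}

#' Fold activation between two replicate groups
#'
#' The ratio of group means of FL/OD with the activator present (`on`) to
#' absent (`off`).
#'
#' @param on,off numeric vectors of replicate FL/OD values.
#' @return `mean(on) / mean(off)`, a single number.
#' @examples
#' fold_activation(c(4500, 4640), c(99, 101))  # 45.7
#' @export
fold_activation <- function(on, off) {
  if (!length(on) || !length(off)) stop("both replicate groups must be non-empty")
  if (anyNA(on) || anyNA(off)) stop("replicate groups contain NA values")
  m_off <- mean(off)
  if (m_off <= 0)
    stop("fold activation undefined: mean of the off group is ", m_off, " (<= 0)")
  mean(on) / m_off
}
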