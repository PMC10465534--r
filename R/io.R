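# File input/output: parameter files (JSON/YAML), tidy plate CSVs,
# assembled sequences (FASTA + JSON report).

#' Read model parameters from a JSON or YAML file
#'
#' The file must contain exactly the [model_params()] field names
#' (`u, k_c, d_A, d_S, d_G, eps, n, a_T, K, lam`); missing fields fall back
#' to the package defaults, unknown fields are an error.
#'
#' @param path a `.json`, `.yaml` or `.yml` file.
#' @return A validated [model_params()] object.
#' @export
read_model_params <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(model_params, as.list(vals))
}

#' Write model parameters to JSON
#'
#' @param params a [model_params()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_params <- function(params, path) {
  validate_model_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a tidy plate CSV
#'
#' Plates travel as UTF-8 comma-separated tables with a header row and `.`
#' decimal marks, one row per well (see [validate_plate()] for the schema).
#'
#' @param path CSV file path.
#' @return `read_plate_csv`: a validated plate data frame.
#' @export
read_plate_csv <- function(path) {
  plate <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_plate(plate)
  plate
}

#' @rdname read_plate_csv
#' @param plate a plate data frame.
#' @return `write_plate_csv`: `path`, invisibly.
#' @export
write_plate_csv <- function(plate, path) {
  utils::write.csv(plate, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an assembled array as FASTA plus a JSON report
#'
#' @param report an `assembly_report` from [assemble_array()].
#' @param fasta,json output paths (either may be `NULL` to skip).
#' @param id FASTA record id.
#' @return The FASTA path, invisibly.
#' @export
write_assembly <- function(report, fasta, json = NULL, id = "array") {
  stopifnot(inherits(report, "assembly_report"))
  if (!is.null(fasta)) {
    dna <- Biostrings::DNAStringSet(report$sequence)
    names(dna) <- sprintf("%s parts=%s", id, paste(report$parts, collapse = ","))
    Biostrings::writeXStringSet(dna, fasta)
  }
  if (!is.null(json)) {
    jsonlite::write_json(list(
      length = nchar(report$sequence),
      parts = report$parts,
      junctions = report$junctions,
      forbidden_sites = report$sites,
      repeats = report$repeats[c("length", "unit", "copies", "score")],
      star_counts = as.list(report$star_counts)),
      json, auto_unbox = TRUE, digits = NA)
  }
  invisible(fasta)
}
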