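# In-silico construction of regulatory RNA array DNA sequences:
# Golden-Gate-style interleaving of STAR and insulator parts with 4-nt
# fusion overhangs, forbidden-site scanning, and direct-repeat risk.

#' A DNA part with fusion overhangs
#'
#' A part carries its full double-stranded sequence including the 4-nt
#' fusion overhangs at both ends. At a junction, adjacent parts share the
#' scar once: the upstream part's downstream overhang must equal the
#' downstream part's upstream overhang, and the assembled sequence keeps a
#' single copy of it (assembled length = sum of part lengths minus 4 per
#' junction).
#'
#' @param id part identifier (e.g. `"STAR50"`).
#' @param category one of `"STAR"`, `"insulator"`, `"promoter"`, `"target"`.
#' @param sequence uppercase DNA over A/C/G/T, including both overhangs.
#' @param overhang_up,overhang_dn the 4-nt fusion overhangs; they must match
#'   the first and last 4 nt of `sequence`.
#' @return A `dna_part` object.
#' @export
dna_part <- function(id, category, sequence,
                     overhang_up = substr(sequence, 1, 4),
                     overhang_dn = substr(sequence, nchar(sequence) - 3,
                                          nchar(sequence))) {
  category <- match.arg(category, c("STAR", "insulator", "promoter", "target"))
  if (!nzchar(sequence) || grepl("[^ACGT]", sequence))
    stop("part sequence must be non-empty uppercase DNA over A/C/G/T")
  if (nchar(overhang_up) != 4 || nchar(overhang_dn) != 4)
    stop("fusion overhangs must be exactly 4 nt")
  if (substr(sequence, 1, 4) != overhang_up ||
      substr(sequence, nchar(sequence) - 3, nchar(sequence)) != overhang_dn)
    stop("overhangs must match the ends of the part sequence")
  structure(list(id = id, category = category, sequence = sequence,
                 overhang_up = overhang_up, overhang_dn = overhang_dn),
            class = "dna_part")
}

#' Read parts from a FASTA file
#'
#' Headers are parsed as `>id category=STAR` (whitespace-separated
#' `key=value` tags; `category` required).
#'
#' @param path FASTA file of uppercase DNA parts.
#' @return A named list of [dna_part()] objects.
#' @export
read_parts_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- lapply(seq_along(seqs), function(i) {
    hdr <- strsplit(names(seqs)[i], "\\s+")[[1]]
    tags <- hdr[-1]
    kv <- strsplit(tags[grepl("=", tags)], "=")
    vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
    if (!"category" %in% names(vals))
      stop("FASTA header for '", hdr[1], "' lacks a category= tag")
    dna_part(hdr[1], vals[["category"]], as.character(seqs[[i]]))
  })
  stats::setNames(parts, vapply(parts, `[[`, "", "id"))
}

# Join parts left to right, sharing each 4-nt scar once; errors on any
# overhang mismatch, reporting the junction.
join_parts <- function(parts) {
  seq <- parts[[1]]$sequence
  junctions <- NULL
  if (length(parts) > 1) for (i in 2:length(parts)) {
    up <- parts[[i - 1]]; dn <- parts[[i]]
    ok <- identical(up$overhang_dn, dn$overhang_up)
    junctions <- rbind(junctions, data.frame(
      position = i - 1L, upstream = up$id, downstream = dn$id,
      overhang = up$overhang_dn, match = ok))
    if (!ok)
      stop("overhang mismatch at junction ", i - 1L, ": ", up$id, " ends ",
           up$overhang_dn, " but ", dn$id, " starts ", dn$overhang_up)
    seq <- paste0(seq, substr(dn$sequence, 5, nchar(dn$sequence)))
  }
  list(sequence = seq, junctions = junctions)
}

#' Assemble a regulatory RNA array sequence
#'
#' Concatenates `copies` repeats of (STAR + insulator) — each STAR followed
#' by its insulator — or an explicit mixed `order` of STAR parts for
#' multiplex arrays, validating every 4-nt fusion overhang. The report
#' includes the per-junction checks, a forbidden-site scan (BsaI by
#' default, the Type IIS enzyme of the cloning scheme), and direct-repeat
#' statistics from [repeat_risk()].
#'
#' @param star a `"STAR"`-category [dna_part()] (ignored when `order` is
#'   given).
#' @param insulator an `"insulator"`-category [dna_part()].
#' @param copies number of STAR copies, 1--8.
#' @param order optional list of STAR parts defining a mixed (multiplex)
#'   array order; each is followed by the insulator.
#' @param enzymes named character vector of recognition sites to scan.
#' @return An `assembly_report` list: `sequence`, `parts` (ids in order),
#'   `junctions`, `sites` (forbidden-site hits), `repeats`, `star_counts`.
#' @export
assemble_array <- function(star, insulator, copies = 1, order = NULL,
                           enzymes = c(BsaI = "GGTCTC")) {
  stopifnot(inherits(insulator, "dna_part"))
  if (insulator$category != "insulator") stop("insulator part has wrong category")
  if (is.null(order)) {
    stopifnot(inherits(star, "dna_part"))
    if (star$category != "STAR") stop("star part has wrong category")
    if (copies < 1 || copies > 8 || copies != round(copies))
      stop("copies must be an integer in [1, 8]")
    order <- rep(list(star), copies)
  } else {
    if (!all(vapply(order, inherits, logical(1), "dna_part")))
      stop("order must be a list of dna_part objects")
    if (length(order) < 1 || length(order) > 8)
      stop("copies must be an integer in [1, 8]")
  }
  parts <- list()
  for (p in order) parts <- c(parts, list(p, insulator))
  joined <- join_parts(parts)
  star_ids <- vapply(order, `[[`, "", "id")
  rep_stats <- repeat_risk(joined$sequence)
  sites <- scan_forbidden_sites(joined$sequence, enzymes)
  structure(list(sequence = joined$sequence,
                 parts = vapply(parts, `[[`, "", "id"),
                 junctions = joined$junctions,
                 sites = sites, repeats = rep_stats,
                 star_counts = c(table(star_ids))), class = "assembly_report")
}

#' @export
print.assembly_report <- function(x, ...) {
  cat("assembled array:", nchar(x$sequence), "bp;",
      length(x$parts), "parts;",
      if (is.null(x$junctions)) 0 else nrow(x$junctions), "junctions ok\n")
  cat("STAR copies:", paste(names(x$star_counts), x$star_counts,
                            sep = " x ", collapse = ", "), "\n")
  cat("forbidden sites:", nrow(x$sites), "; longest direct repeat:",
      x$repeats$length, "nt x", x$repeats$copies, "\n")
  invisible(x)
}

# Expand one IUPAC site to a fixed-width regular expression; errors on
# invalid codes.
iupac_ok <- function(site) grepl("^[ACGTRYSWKMBDHVN]+$", site)

#' Scan a sequence for enzyme recognition sites on both strands
#'
#' Reports every occurrence of each (IUPAC) recognition sequence on the
#' given strand and on the reverse complement, in 0-based half-open
#' top-strand coordinates. A palindromic site matches both strands at the
#' same locus and is reported once.
#'
#' @param seq a DNA string.
#' @param enzymes named character vector of IUPAC recognition sites.
#' @return A data frame with columns `enzyme`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @export
scan_forbidden_sites <- function(seq, enzymes = c(BsaI = "GGTCTC")) {
  if (any(!iupac_ok(enzymes)))
    stop("invalid IUPAC code in recognition site(s): ",
         paste(enzymes[!iupac_ok(enzymes)], collapse = ", "))
  if (is.null(names(enzymes))) names(enzymes) <- enzymes
  subject <- Biostrings::DNAString(seq)
  out <- NULL
  for (i in seq_along(enzymes)) {
    pat <- Biostrings::DNAString(enzymes[[i]])
    fwd <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
    rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                    subject, fixed = FALSE)
    hits <- rbind(
      if (length(fwd)) data.frame(start = Biostrings::start(fwd) - 1L,
                                  end = Biostrings::end(fwd), strand = "+"),
      if (length(rev)) data.frame(start = Biostrings::start(rev) - 1L,
                                  end = Biostrings::end(rev), strand = "-"))
    if (is.null(hits)) next
    hits$enzyme <- names(enzymes)[i]
    # a palindromic site hits both strands at one locus: keep one record
    key <- paste(hits$start, hits$end)
    dup_keys <- unique(key[duplicated(key)])
    hits$strand[key %in% dup_keys] <- "both"
    hits <- hits[!duplicated(key), ]
    out <- rbind(out, hits[, c("enzyme", "start", "end", "strand")])
  }
  if (is.null(out))
    out <- data.frame(enzyme = character(), start = integer(),
                      end = integer(), strand = character())
  out[order(out$enzyme, out$start), , drop = FALSE]
}

#' Direct-repeat risk of a sequence
#'
#' Finds the longest exactly repeated substring via suffix sorting (adjacent
#' longest-common-prefix of the sorted suffixes) and counts its occurrences.
#' Long high-copy repeats flag recombination-prone constructs — tandem RNA
#' arrays are repetitive by design, so the score (repeat length x copy
#' count) quantifies how much repeated sequence an assembly carries.
#'
#' @param seq a DNA string (length >= 0; trivial inputs give a zero report).
#' @return A list: `length` (longest repeat length), `unit` (the repeated
#'   substring), `copies` (occurrences, overlaps allowed), `positions`
#'   (0-based starts), `score` (`length * copies`).
#' @export
repeat_risk <- function(seq) {
  n <- nchar(seq)
  if (n < 2)
    return(list(length = 0L, unit = "", copies = 0L,
                positions = integer(), score = 0))
  suff <- substring(seq, 1:n, n)
  ord <- order(suff, method = "radix")
  best_len <- 0L; best_at <- 1L
  prev <- suff[ord[1]]
  for (i in 2:n) {
    cur <- suff[ord[i]]
    l <- common_prefix_len(prev, cur)
    if (l > best_len) { best_len <- l; best_at <- ord[i] }
    prev <- cur
  }
  if (best_len == 0L)
    return(list(length = 0L, unit = "", copies = 0L,
                positions = integer(), score = 0))
  unit <- substr(seq, best_at, best_at + best_len - 1L)
  pos <- find_all_occurrences(seq, unit)
  list(length = best_len, unit = unit, copies = length(pos),
       positions = pos, score = best_len * length(pos))
}

# Length of the common prefix of two strings.
common_prefix_len <- function(a, b) {
  m <- min(nchar(a), nchar(b))
  if (m == 0) return(0L)
  av <- utf8ToInt(substr(a, 1, m)); bv <- utf8ToInt(substr(b, 1, m))
  neq <- which(av != bv)
  if (length(neq)) neq[1] - 1L else m
}

#' Count (possibly overlapping) occurrences of a subsequence
#'
#' Fixed-string scan of the top strand; used to verify assemblies (e.g. an
#' x4 homogeneous array contains its STAR exactly 4 times).
#'
#' @param seq a DNA string.
#' @param unit the subsequence to count.
#' @return Number of occurrences (overlaps allowed).
#' @export
count_subsequence <- function(seq, unit) length(find_all_occurrences(seq, unit))

# All (possibly overlapping) 0-based start positions of `unit` in `seq`.
find_all_occurrences <- function(seq, unit) {
  pos <- integer(); from <- 1L
  repeat {
    hit <- regexpr(unit, substr(seq, from, nchar(seq)), fixed = TRUE)
    if (hit == -1L) break
    at <- from + as.integer(hit) - 1L
    pos <- c(pos, at - 1L)
    from <- at + 1L
  }
  pos
}
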