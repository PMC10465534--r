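test_that("parts validate sequences and overhangs", {
  expect_s3_class(make_star(), "dna_part")
  expect_error(dna_part("x", "STAR", "acgt"), "uppercase DNA")
  expect_error(dna_part("x", "STAR", "AATGNNNNGCTT"), "uppercase DNA")
  expect_error(dna_part("x", "STAR", "AATGCCCGCTT", overhang_up = "AAT"), "4 nt")
  expect_error(dna_part("x", "nope", "AATGCCCGCTT"), "arg")
})

test_that("assembly length, composition, and junction checks", {
  star <- make_star(); ins <- make_insulator()
  # copies = 1: one junction, one shared 4-nt scar
  r1 <- assemble_array(star, ins, copies = 1)
  expect_equal(nchar(r1$sequence),
               nchar(star$sequence) + nchar(ins$sequence) - 4)
  # copies = 4 homogeneous: exactly 4 STAR occurrences by substring scan
  r4 <- assemble_array(star, ins, copies = 4)
  expect_equal(count_subsequence(r4$sequence, star$sequence), 4)
  expect_equal(nrow(r4$junctions), 7)
  expect_true(all(r4$junctions$match))
  expect_equal(nchar(r4$sequence),
               4 * (nchar(star$sequence) + nchar(ins$sequence)) - 7 * 4)
  # mixed multiplex order: per-variant counts in the report
  s10 <- make_star("STAR10", strrep("GATTC", 12))
  s50 <- make_star("STAR50", strrep("CCATG", 12))
  rm <- assemble_array(insulator = ins, order = list(s10, s10, s50))
  expect_equal(unname(rm$star_counts[c("STAR10", "STAR50")]), c(2L, 1L))
  expect_error(assemble_array(star, ins, copies = 9), "\\[1, 8\\]")
  # overhang mismatch is reported with the junction
  bad_ins <- dna_part("bad", "insulator", paste0("TTTT", strrep("CTGA", 7), "AATG"))
  expect_error(assemble_array(star, bad_ins, copies = 2), "overhang mismatch")
})

test_that("assembly is deterministic and associative over the block list", {
  star <- make_star(); ins <- make_insulator()
  a <- assemble_array(star, ins, copies = 3)$sequence
  b <- assemble_array(star, ins, copies = 3)$sequence
  expect_identical(a, b)
  # assembling x1 then extending equals assembling x2 directly
  one <- assemble_array(star, ins, copies = 1)$sequence
  two <- assemble_array(star, ins, copies = 2)$sequence
  expect_identical(two, paste0(one, substring(one, 5)))
})

test_that("forbidden-site scan reports both strands in 0-based half-open coords", {
  backbone <- strrep("AC", 40)
  seq <- paste0(substr(backbone, 1, 20), "GGTCTC", substr(backbone, 21, 80))
  hits <- scan_forbidden_sites(seq, c(BsaI = "GGTCTC"))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 20)
  expect_equal(hits$end, 26)
  expect_equal(hits$strand, "+")
  expect_equal(substr(seq, hits$start + 1, hits$end), "GGTCTC")
  # reverse-strand site
  seq_rc <- paste0(substr(backbone, 1, 20), "GAGACC", substr(backbone, 21, 80))
  hits_rc <- scan_forbidden_sites(seq_rc, c(BsaI = "GGTCTC"))
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$start, 20)
  # absent site: empty result
  expect_equal(nrow(scan_forbidden_sites(backbone, c(BsaI = "GGTCTC"))), 0)
  # palindromic site: one deduplicated hit per locus
  seq_pal <- paste0(substr(backbone, 1, 10), "GAATTC", substr(backbone, 11, 80))
  hits_pal <- scan_forbidden_sites(seq_pal, c(EcoRI = "GAATTC"))
  expect_equal(nrow(hits_pal), 1)
  expect_equal(hits_pal$strand, "both")
  # IUPAC degenerate site and invalid code
  expect_equal(nrow(scan_forbidden_sites("AAGGACCAA", c(x = "GGWCC"))), 1)
  expect_error(scan_forbidden_sites("ACGT", c(x = "GGXCC")), "IUPAC")
})

test_that("repeat finder agrees with quadratic brute force on small inputs", {
  withr::with_seed(19, for (i in 1:8) {
    seq <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
    expect_equal(repeat_risk(seq)$length, oracle_longest_repeat(seq))
  })
  # planted repeat
  unit <- "GATTACAGATTACA"
  seq <- paste0(strrep("C", 30), unit, strrep("A", 25), unit, strrep("G", 30))
  rr <- repeat_risk(seq)
  expect_gte(rr$length, nchar(unit))
  expect_true(grepl(rr$unit, seq, fixed = TRUE))
})

test_that("tandem arrays report the expected repeat structure", {
  star <- make_star("S", paste(rep(c("GAC", "TTG", "CAA", "AGT"), 5), collapse = ""))
  ins <- make_insulator()
  r8 <- assemble_array(star, ins, copies = 8)
  unit_len <- nchar(star$sequence) + nchar(ins$sequence) - 4
  # the repeat unit (STAR + insulator) occurs 8 times
  unit <- substring(r8$sequence, 1, unit_len)
  expect_equal(count_subsequence(r8$sequence, unit), 8)
  expect_equal(r8$repeats$score, r8$repeats$length * r8$repeats$copies)
  # random 1 kb sequence: longest repeat is short
  rand_seq <- withr::with_seed(5, paste(sample(c("A", "C", "G", "T"), 1000,
                                               replace = TRUE), collapse = ""))
  expect_lt(repeat_risk(rand_seq)$length, 20)
  # degenerate inputs
  expect_equal(repeat_risk("A")$length, 0)
  expect_equal(repeat_risk("")$score, 0)
  expect_equal(repeat_risk("AA")$length, 1)
})

test_that("parts read from FASTA and assemblies write FASTA + JSON", {
  fa <- system.file("extdata", "synthetic_parts.fa", package = "starkit")
  parts <- read_parts_fasta(fa)
  expect_setequal(names(parts),
                  c("STAR50", "STAR10", "PlmJ", "csy4hp", "shcsy4hp"))
  expect_equal(parts$STAR50$category, "STAR")
  expect_equal(parts$shcsy4hp$category, "insulator")
  rep4 <- assemble_array(parts$STAR50, parts$shcsy4hp, copies = 4)
  expect_equal(unname(rep4$star_counts["STAR50"]), 4L)
  out_fa <- tempfile(fileext = ".fa"); out_js <- tempfile(fileext = ".json")
  write_assembly(rep4, out_fa, out_js)
  back <- Biostrings::readDNAStringSet(out_fa)
  expect_equal(as.character(back[[1]]), rep4$sequence)
  js <- jsonlite::read_json(out_js, simplifyVector = TRUE)
  expect_equal(js$length, nchar(rep4$sequence))
})
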