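test_that("reactivity TSV reading returns values as-is and fills gaps with the sentinel", {
  f <- withr::local_tempfile()
  writeLines(c("1\t0.2", "2\t1.5", "3\t-0.1"), f)
  p <- read_reactivity_tsv(f)
  expect_equal(p$values, c(0.2, 1.5, -0.1))
  expect_equal(p$length, 3L)

  writeLines(c("# comment", "1\t0.2", "3\t0.4"), f)
  p <- read_reactivity_tsv(f)
  expect_equal(p$values, c(0.2, -10, 0.4))
})

test_that("malformed and duplicate reactivity rows are rejected with locations", {
  f <- withr::local_tempfile()
  writeLines(c("1\t0.2", "2\tabc"), f)
  expect_error(read_reactivity_tsv(f), "line 2")
  writeLines(c("1\t0.2", "1\t0.3"), f)
  expect_error(read_reactivity_tsv(f), "duplicate position 1")
})

test_that("reactivity profiles round-trip through TSV", {
  set.seed(11)
  v <- round(c(stats::rexp(40), -10, -0.25, 0), 6)
  p <- reactivity_profile(v, "rna1", "c1", "r1")
  f <- withr::local_tempfile()
  write_reactivity_tsv(p, f)
  expect_equal(read_reactivity_tsv(f)$values, v)
})

test_that("dot-bracket parsing matches matched-parenthesis semantics", {
  s <- parse_dotbracket("((...))")
  expect_equal(s$pairs, rbind(c(1L, 7L), c(2L, 6L)))
  expect_equal(NROW(parse_dotbracket(".......")$pairs), 0L)
  expect_error(parse_dotbracket("(.))"), "index 4")
  expect_error(parse_dotbracket("((."), "index 1")
})

test_that("dot-bracket serialization round-trips on random structures", {
  set.seed(21)
  for (k in 1:20) {
    s <- random_structure(sample(10:60, 1))
    expect_equal(parse_dotbracket(as_dotbracket(s))$pairs, s$pairs)
  }
})

test_that("structure invariants are enforced", {
  expect_error(secondary_structure(10, rbind(c(2, 6), c(4, 8))), "crossing")
  expect_error(secondary_structure(10, rbind(c(1, 6), c(6, 10))),
               "more than one pair")
  expect_error(secondary_structure(10, rbind(c(1, 4))), "hairpin")
  expect_silent(secondary_structure(10, rbind(c(1, 5))))
})

test_that("dbn files round-trip with sequence", {
  s <- secondary_structure(9, rbind(c(1, 9), c(2, 8)),
                           sequence = "GGGAAACCC", min_hairpin = 3)
  f <- withr::local_tempfile()
  write_dotbracket(s, f, name = "toy")
  r <- read_dotbracket(f)
  expect_equal(r$pairs, s$pairs)
  expect_equal(r$sequence, "GGGAAACCC")
})

test_that("reactivity classes follow the closed-interval boundary convention", {
  sch <- class_scheme()
  expect_equal(reactivity_class(0.39, sch), "low")
  expect_equal(reactivity_class(-10, sch), "undefined")
  expect_equal(reactivity_class(0.4, sch), "medium")
  expect_equal(reactivity_class(0.7, sch), "medium")
  expect_equal(reactivity_class(0.71, sch), "high")
  # classes partition every input
  v <- c(-10, seq(-0.5, 2, by = 0.01))
  expect_true(all(reactivity_class(v, sch) %in%
                    c("undefined", "low", "medium", "high")))
})

test_that("color annotation files carry position, value and class", {
  f <- withr::local_tempfile()
  write_color_annotation(c(0.39, -10, 0.7, 1.2), f)
  lines <- readLines(f)
  expect_equal(lines[1], "position\tvalue\tclass")
  expect_match(lines[2], "low$")
  expect_match(lines[3], "undefined$")
  expect_match(lines[4], "medium$")
  expect_match(lines[5], "high$")
  expect_error(write_color_annotation(c(0.1, 0.2), f, length = 3),
               "does not match")
  write_color_annotation(c(0.39, -10), f, values_only = TRUE)
  expect_equal(readLines(f), c("0.39", "-10"))
})

test_that("samples tables round-trip, enforce uniqueness and respect discarded", {
  df <- data.frame(rna_id = "r1", probe = "1M7", condition = c("mg", "mg"),
                   replicate = c("1", "2"), primer_start = 1L,
                   primer_end = 60L, file_path = c("a.tsv", "b.tsv"),
                   experimentalist = "ph", discarded = c(FALSE, TRUE))
  f <- withr::local_tempfile()
  write_samples_table(df, f)
  r <- read_samples_table(f)
  expect_equal(r$replicate, c(1L, 2L))
  expect_equal(nrow(active_samples(r)), 1L)
  df$replicate <- c("1", "1")
  write_samples_table(df, f)
  expect_error(read_samples_table(f), "duplicate sample row")
})

test_that("FASTA and MSA files round-trip with T-to-U conversion", {
  f <- withr::local_tempfile()
  write_fasta_sequences(c(ref = "GGCAT-", seq1 = "GGCAU-"), f)
  aln <- read_msa_fasta(f)
  expect_equal(unname(aln$sequences["ref"]), "GGCAU-")
  expect_equal(aln$reference, "ref")
  expect_error(msa(c(a = "ACGU", b = "ACG")), "differ in length")
  expect_error(msa(c(a = "ACGU", b = "ACGU"), reference = "zz"), "absent")
})
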