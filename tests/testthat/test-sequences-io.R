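test_that("FASTA parsing preserves order, uppercases and auto-detects", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "acgt", ">s2 some description", "GT"), f)
  s <- read_fasta(f)
  expect_s3_class(s, "mlcs_seqset")
  expect_equal(s$n, 2L)
  expect_equal(s$ids, c("s1", "s2"))
  expect_equal(s$residues, c("ACGT", "GT"))
  expect_equal(s$lengths, c(4L, 2L))
  expect_equal(s$alphabet$name, "dna")

  writeLines(c(">p1", "MKV", ">p2", "MKL"), f)
  expect_equal(read_fasta(f)$alphabet$name, "protein")
})

test_that("FASTA errors carry class and location", {
  expect_error(read_fasta(tempfile()), class = "mlcs_input_error")

  f <- withr::local_tempfile(fileext = ".fasta")
  file.create(f)
  expect_error(read_fasta(f), "empty", class = "mlcs_input_error")

  writeLines(c(">only", "ACGT"), f)
  err <- tryCatch(read_fasta(f), error = identity)
  expect_s3_class(err, "mlcs_cardinality_error")
  expect_match(conditionMessage(err), "1 record")

  writeLines(c("ACGT", ">s1", "ACGT"), f)
  expect_error(read_fasta(f), "line 1", class = "mlcs_parse_error")

  writeLines(c(">s1", ">s2", "ACGT"), f)
  expect_error(read_fasta(f), "line 1", class = "mlcs_parse_error")
})

test_that("validation reports violations as data, not exceptions", {
  ok <- validate_sequences(sequence_set(c("ACGT", "TTGA"), alphabet = "dna"))
  expect_true(ok$pass)
  expect_equal(nrow(ok$violations), 0L)

  bad <- validate_sequences(sequence_set(c("ACGU", "TTGA"), alphabet = "dna"))
  expect_false(bad$pass)
  expect_equal(bad$violations$id, "seq1")
  expect_equal(bad$violations$position, 4L)
  expect_equal(bad$violations$symbol, "U")

  expect_true(validate_sequences(
    sequence_set(c("MKV", "MKL"), alphabet = "protein"))$pass)
})

test_that("alphabets are fixed sets; ambiguity codes need explicit extension", {
  expect_equal(length(mlcs_alphabet("dna")$symbols), 4L)
  expect_equal(length(mlcs_alphabet("protein")$symbols), 20L)
  expect_false("N" %in% mlcs_alphabet("dna")$symbols)
  expect_true("N" %in% mlcs_alphabet("dna", extra = "N")$symbols)
  expect_false(validate_sequences(
    sequence_set(c("ACGN", "ACGT"), alphabet = "dna"))$pass)
  expect_true(validate_sequences(
    sequence_set(c("ACGN", "ACGT"),
                 alphabet = mlcs_alphabet("dna", extra = "N")))$pass)
})

test_that("random generation is seed-deterministic and seed-sensitive", {
  a <- generate_random_sequences(3, 10, "dna", seed = 1)
  b <- generate_random_sequences(3, 10, "dna", seed = 1)
  expect_identical(a$residues, b$residues)
  c3 <- generate_random_sequences(2, 50, "dna", seed = 2)
  d <- generate_random_sequences(2, 50, "dna", seed = 3)
  expect_false(identical(c3$residues, d$residues))
  expect_error(generate_random_sequences(1, 5, "dna", 1),
               class = "mlcs_parameter_error")
  expect_error(generate_random_sequences(2, 0, "dna", 1),
               class = "mlcs_parameter_error")
  # every generated set validates and a dna set auto-detects as dna
  for (seed in 1:10) {
    g <- generate_random_sequences(3, 20, "dna", seed = seed)
    expect_true(validate_sequences(g)$pass)
    expect_equal(detect_alphabet(g$residues)$name, "dna")
  }
})

test_that("report files are deterministic and round out the pipeline", {
  r <- result_report(worked_strings, 4L)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_report(r, f1); write_report(r, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(readLines(f1),
               c("BCAB", "BCBA", "BDAB", "length: 4", "count: 3"))

  empty <- result_report(character(), 0L)
  write_report(empty, f1)
  expect_equal(readLines(f1), c("length: 0", "count: 0"))
})

test_that("parse -> write -> parse is idempotent on sequence content", {
  s <- generate_random_sequences(4, 33, "dna", seed = 11)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(s, f)
  s2 <- read_fasta(f)
  expect_identical(s2$residues, s$residues)
  expect_identical(s2$ids, s$ids)
  expect_identical(s2$alphabet$name, s$alphabet$name)
})

test_that("sequence sets need at least two sequences", {
  err <- tryCatch(sequence_set("ACGT"), error = identity)
  expect_s3_class(err, "mlcs_cardinality_error")
  expect_match(conditionMessage(err), "got 1")
})
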