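make_db <- function(len = 4000, seed = 5, gc = 0.5) {
  withr::with_seed(seed, reference_db(c(chrTest = random_dna(len, gc))))
}

test_that("verbatim substrings classify as canonical, transformed as swinger", {
  db <- make_db()
  ref <- db$sequences[["chrTest"]]
  frag <- substr(ref, 1001, 1200)

  hit <- detect_swinger(frag, db)
  expect_equal(hit$classification, "canonical")
  expect_equal(hit$detection_transformation, "identity")
  expect_equal(c(hit$ref_start, hit$ref_end), c(1001L, 1200L))
  expect_equal(hit$percent_identity, 100)
  expect_equal(hit$strand, "+")

  swinger <- apply_transformation("A<>T", frag)
  hit <- detect_swinger(swinger, db)
  expect_equal(hit$classification, "swinger")
  expect_equal(hit$detection_transformation, parse_transformation("A<>T")$name)
  expect_equal(hit$transcription_transformation, parse_transformation("A<>T")$name)
  expect_equal(c(hit$ref_start, hit$ref_end), c(1001L, 1200L))
  expect_equal(hit$percent_identity, 100)
})

test_that("asymmetric detection reports the inverse as the transcription exchange", {
  db <- make_db()
  frag <- substr(db$sequences[["chrTest"]], 2001, 2300)
  # a template transcribed with exchange t yields read = t(template); the
  # detector must apply t^-1 to recover it and report transcription = t
  t <- parse_transformation("A-G-C-T-A")
  read <- apply_transformation(t, frag)
  hit <- detect_swinger(read, db)
  expect_equal(hit$classification, "swinger")
  expect_equal(hit$detection_transformation, invert_transformation(t)$name)
  expect_equal(hit$transcription_transformation, t$name)
})

test_that("reads below the length threshold come back unidentified", {
  db <- make_db()
  withr::with_seed(9, {
    short <- random_dna(30)
  })
  hit <- detect_swinger(short, db)
  expect_equal(hit$classification, "unidentified")
  expect_true(is.na(hit$reference_id))
  expect_true(is.na(hit$percent_identity))
})

test_that("strand duality relates the two descriptions by complement conjugation", {
  # reverse-complementing a read moves its template to the other strand;
  # the reported transcription exchange must conjugate by the complement
  # map (and is unchanged exactly when the exchange commutes with it,
  # e.g. A<>T), while the template locus stays fixed
  db <- make_db()
  frag <- substr(db$sequences[["chrTest"]], 501, 700)
  cc <- complement_transformation()
  for (nm in c("A<>T", "A<>C", "A-T-C-G-A", "A-C-G-A")) {
    read <- apply_transformation(nm, frag)
    fwd <- detect_swinger(read, db)
    rev <- detect_swinger(reverse_complement(read), db)
    conj <- compose_transformations(
      cc, compose_transformations(fwd$transcription_transformation, cc))
    expect_equal(rev$transcription_transformation, conj$name)
    expect_equal(c(rev$ref_start, rev$ref_end), c(fwd$ref_start, fwd$ref_end))
    expect_setequal(c(rev$strand, fwd$strand), c("-", "+"))
    expect_equal(fwd$transcription_transformation,
                 parse_transformation(nm)$name)
  }
})

test_that("detection agrees with the exhaustive oracle on small references", {
  withr::with_seed(31, {
    refs <- c(refA = random_dna(200), refB = random_dna(150))
    db <- reference_db(refs)
    params <- detection_params(min_aligned_length = 20, canonical_first = FALSE)
    for (rep in 1:12) {
      t_name <- sample(c("identity", names(swinger_transformations())), 1)
      ref_i <- sample(1:2, 1)
      len <- sample(30:50, 1)
      start <- sample(1:(nchar(refs[[ref_i]]) - len + 1), 1)
      template <- substr(refs[[ref_i]], start, start + len - 1)
      if (runif(1) < 0.5) template <- reverse_complement(template)
      read <- apply_transformation(t_name, template)

      hit <- detect_swinger(read, db, params)
      oracle <- oracle_detect(read, refs)
      expect_equal(hit$score, oracle$score)            # 2 * len for exact plants
      expect_equal(hit$score, 2L * len)
      expect_true(hit$detection_transformation %in% oracle$transformations)
    }
  })
})

test_that("batch detection preserves order, counts classes and handles empties", {
  db <- make_db(3000, seed = 6)
  ref <- db$sequences[["chrTest"]]
  withr::with_seed(32, {
    starts <- sample(1:2800, 10)
  })
  reads <- character(10)
  for (i in 1:10) {
    frag <- substr(ref, starts[i], starts[i] + 149)
    reads[i] <- if (i <= 5) frag else apply_transformation("A<>T", frag)
  }
  names(reads) <- paste0("r", 1:10)
  hits <- suppressMessages(batch_detect(reads, db))
  expect_equal(hits$read_id, names(reads))
  expect_equal(unname(table(hits$classification)[c("canonical", "swinger")]),
               c(5L, 5L), ignore_attr = TRUE)
  expect_message(batch_detect(reads[0], db), "0 reads")
  empty <- suppressMessages(batch_detect(reads[0], db))
  expect_equal(nrow(empty), 0L)
})

test_that("invalid inputs are rejected with informative errors", {
  db <- make_db(500, seed = 7)
  expect_error(reference_db(character(0)), "empty")
  expect_error(reference_db(c(a = "ACGT", a = "ACGT")), "unique")
  expect_error(detect_swinger("", db), "non-empty")
  expect_error(detect_swinger("ACGT!!", db), "invalid character")
})

test_that("hit tables round-trip through TSV and tabular import maps columns", {
  db <- make_db(2000, seed = 8)
  frag <- substr(db$sequences[["chrTest"]], 101, 260)
  hits <- suppressMessages(
    batch_detect(c(x1 = apply_transformation("C<>T", frag)), db))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits(hits, path)
  back <- read_hits(path)
  expect_equal(back$read_id, hits$read_id)
  expect_equal(back$score, hits$score)
  expect_equal(back$transcription_transformation,
               hits$transcription_transformation)

  tab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(
    c("q1", "s1", "97.5", "200", "5", "0", "1", "200", "500", "301",
      "1e-50", "180", "A<>T"), collapse = "\t"), tab)
  imp <- import_tabular_hits(tab)
  expect_equal(imp$strand, "-")
  expect_equal(c(imp$ref_start, imp$ref_end), c(301L, 500L))
  expect_equal(imp$classification, "swinger")
  expect_equal(imp$detection_transformation, parse_transformation("A<>T")$name)
})
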