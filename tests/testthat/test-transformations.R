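test_that("exactly 23 non-identity bijections enumerate, with the expected kinds", {
  tr <- swinger_transformations()
  expect_length(tr, 23L)
  kinds <- vapply(tr, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "symmetric"), 9L)
  expect_equal(sum(kinds == "asymmetric"), 14L)
  expect_false("identity" %in% names(tr))
  expect_equal(anyDuplicated(names(tr)), 0L)
  # symmetric block first, both blocks sorted
  expect_equal(kinds, c(rep("symmetric", 9), rep("asymmetric", 14)),
               ignore_attr = TRUE)
})

test_that("cycle-type tally matches brute force over all 24 permutations", {
  # independent oracle: classify every permutation of a 4-set by cycle type
  perms <- oracle_permutations()
  cyc_len <- function(mapping) {
    lens <- integer(0)
    seen <- character(0)
    for (b in c("A", "C", "G", "T")) {
      if (b %in% seen) next
      cyc <- b
      nxt <- mapping[[b]]
      while (nxt != b) { cyc <- c(cyc, nxt); nxt <- mapping[[nxt]] }
      seen <- c(seen, cyc)
      if (length(cyc) > 1) lens <- c(lens, length(cyc))
    }
    if (length(lens) == 0) "identity"
    else paste(sort(lens), collapse = "+")
  }
  oracle_tally <- table(vapply(perms, cyc_len, character(1)))
  expect_equal(unname(oracle_tally[["identity"]]), 1L)

  tr <- swinger_transformations()
  got <- table(vapply(tr, `[[`, character(1), "cycle_type"))
  expect_equal(unname(got[["2-cycle"]]), unname(oracle_tally[["2"]]))      # 6
  expect_equal(unname(got[["2+2-cycle"]]), unname(oracle_tally[["2+2"]]))  # 3
  expect_equal(unname(got[["3-cycle"]]), unname(oracle_tally[["3"]]))     # 8
  expect_equal(unname(got[["4-cycle"]]), unname(oracle_tally[["4"]]))     # 6
  # and the mappings themselves cover all non-identity permutations
  key <- function(m) paste(m[c("A", "C", "G", "T")], collapse = "")
  expect_setequal(vapply(tr, function(t) key(t$mapping), character(1)),
                  setdiff(vapply(perms, key, character(1)), "ACGT"))
})

test_that("canonical names round-trip through the parser", {
  for (t in swinger_transformations()) {
    back <- parse_transformation(t$name)
    expect_identical(back$mapping, t$mapping)
    expect_identical(back$name, t$name)
  }
  # ASCII aliases and loose whitespace
  expect_identical(parse_transformation("A <> T")$name,
                   parse_transformation("A↔T")$name)
  expect_identical(parse_transformation("A-T-C-G-A")$name,
                   parse_transformation("A → T → C → G→ A")$name)
  expect_error(parse_transformation("A<>B"), "cannot parse")
  expect_error(parse_transformation("A-T-A"), "cannot parse")
})

test_that("apply_transformation follows the mapping and preserves length", {
  expect_identical(apply_transformation("A<>T", "GATTACA"), "GTAATCT")
  expect_identical(apply_transformation("A-T-C-G-A", "ACGT"), "TGAC")
  expect_identical(apply_transformation("C<>G", "AANTT"), "AANTT")
  # lowercase and RNA normalize: gauu -> GATT -> swap A/T -> GTAA
  expect_identical(apply_transformation("A<>T", "gauu"), "GTAA")
  withr::with_seed(7, {
    s <- random_dna(500)
    for (t in swinger_transformations()) {
      out <- apply_transformation(t, s)
      expect_identical(nchar(out), nchar(s))
      expect_false(grepl("[^ACGT]", out))
      expect_identical(apply_transformation(t, apply_transformation(invert_transformation(t), s)), s)
    }
  })
})

test_that("IUPAC ambiguity codes map to the image of their base set", {
  # A<>G sends R = {A,G} to itself and Y = {C,T} to itself
  expect_identical(apply_transformation("A<>G", "RY"), "RY")
  # A<>C sends R = {A,G} to {C,G} = S, and M = {A,C} to itself
  expect_identical(apply_transformation("A<>C", "RM"), "SM")
  # N is all four bases, hence always fixed
  for (t in swinger_transformations())
    expect_identical(apply_transformation(t, "N"), "N")
  expect_error(apply_transformation("A<>T", "ACGXZT"),
               "invalid character.*position 4")
})

test_that("inversion follows the group structure", {
  # the published inverse-pair of four-cycles
  expect_identical(invert_transformation("A-T-C-G-A")$name,
                   parse_transformation("A-G-C-T-A")$name)
  for (t in swinger_transformations()) {
    inv <- invert_transformation(t)
    if (t$kind == "symmetric") expect_identical(inv$name, t$name)
    else expect_false(identical(inv$name, t$name))
    expect_identical(invert_transformation(inv)$name, t$name)
    expect_identical(compose_transformations(t, inv)$name, "identity")
  }
})

test_that("composition is closed over the 23 + identity", {
  all24 <- c(list(identity_transformation()), swinger_transformations())
  known <- c("identity", names(swinger_transformations()))
  for (a in all24) for (b in all24) {
    expect_true(compose_transformations(a, b)$name %in% known)
  }
  expect_identical(compose_transformations("A<>T", "C<>G")$name,
                   complement_transformation()$name)
  # conjugating A<>C by the complement map gives G<>T
  cc <- complement_transformation()
  expect_identical(
    compose_transformations(cc, compose_transformations("A<>C", cc))$name,
    parse_transformation("G<>T")$name)
})

test_that("transformation commutes with reverse complement via conjugation", {
  cc <- complement_transformation()
  withr::with_seed(11, {
    for (rep in 1:3) {
      s <- random_dna(200)
      for (t in swinger_transformations()) {
        conj <- compose_transformations(cc, compose_transformations(t, cc))
        expect_identical(reverse_complement(apply_transformation(t, s)),
                         apply_transformation(conj, reverse_complement(s)))
      }
    }
  })
})

test_that("the exported transformation table is complete and writable", {
  tab <- transformation_table()
  expect_equal(nrow(tab), 23L)
  expect_named(tab, c("name", "kind", "cycle_type", "A", "C", "G", "T"))
  # every row's image letters are a permutation of ACGT
  imgs <- apply(tab[, c("A", "C", "G", "T")], 1, function(x)
    paste(sort(x), collapse = ""))
  expect_true(all(imgs == "ACGT"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_transformation_table(path)
  back <- utils::read.delim(path, encoding = "UTF-8")
  expect_equal(nrow(back), 23L)
})
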