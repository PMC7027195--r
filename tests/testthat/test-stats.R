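test_that("exact sign test matches the closed forms and published values", {
  expect_equal(sign_test(38, 43)$p, 0.00106, tolerance = 0.01)
  expect_equal(sign_test(33, 33)$p, (2 / 3)^33)  # 1.545e-6 exactly
  expect_equal(sign_test(0, 10)$p, 1)
  expect_equal(sign_test(5, 5, 0.5)$p, 0.5^5)
  expect_error(sign_test(6, 5))
})

test_that("sign test agrees with the binomial upper tail for all k, n <= 60", {
  for (n in 1:60) {
    k <- 0:n
    ours <- vapply(k, function(kk) sign_test(kk, n)$p, numeric(1))
    oracle <- stats::pbinom(k - 1, n, 2 / 3, lower.tail = FALSE)
    expect_equal(ours, oracle, tolerance = 1e-12)
  }
  # deep tail stays accurate (no catastrophic cancellation)
  expect_equal(sign_test(60, 60, 2 / 3)$p, (2 / 3)^60, tolerance = 1e-12)
})

test_that("abundance-length correlation reproduces the published statistics", {
  s <- data.frame(abundance = c(219, 2, 1, 1, 124),
                  mean_aligned_length = c(325, 225, 196, 152, 308))
  res <- abundance_length_correlation(s)
  expect_equal(res$r, 0.96, tolerance = 0.005)
  expect_equal(res$p, 0.00945, tolerance = 0.02)
  expect_equal(res$n, 5L)
  # r is invariant to the logarithm base
  res_e <- abundance_length_correlation(s, base = exp(1))
  expect_equal(res_e$r, res$r)
  # and matches the t-transform computed by cor.test
  ct <- stats::cor.test(log10(s$abundance), s$mean_aligned_length)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-9)
})

test_that("degenerate correlation inputs are rejected", {
  s2 <- data.frame(abundance = c(10, 5), mean_aligned_length = c(100, 50))
  expect_error(abundance_length_correlation(s2), "at least 3")
  # exactly log-linear classes give r = 1
  s3 <- data.frame(abundance = c(10, 100, 1000),
                   mean_aligned_length = c(100, 200, 300))
  expect_equal(abundance_length_correlation(s3)$r, 1)
  expect_equal(abundance_length_correlation(s3)$p, 0)
})

test_that("class summaries aggregate hits per transformation", {
  hits <- data.frame(
    transcription_transformation = c("A↔T", "A↔T", "A→T→C→G→A", "identity", NA),
    aligned_length = c(100, 300, 250, 80, NA),
    percent_identity = c(95, 99, 97, 100, NA),
    stringsAsFactors = FALSE
  )
  s <- class_summaries(hits)
  expect_equal(nrow(s), 2L)
  at <- s[s$transformation == "A↔T", ]
  expect_equal(at$abundance, 2L)
  expect_equal(at$mean_aligned_length, 200)
  expect_equal(at$mean_percent_identity, 97)
  # zero-filled view covers all 23 classes in enumeration order
  sz <- class_summaries(hits, include_zero = TRUE)
  expect_equal(nrow(sz), 23L)
  expect_equal(sz$transformation, names(swinger_transformations()))
  expect_equal(sum(sz$abundance), 3L)
  expect_equal(nrow(class_summaries(hits[0, ])), 0L)
})

test_that("conservation index matches an independent codon-by-codon oracle", {
  skip_if_not_installed("seqinr")
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  oracle_index <- function(mapping) {
    translate1 <- function(codon)
      seqinr::translate(strsplit(codon, "")[[1]])
    mean(vapply(codons, function(cd) {
      tr <- paste(mapping[strsplit(cd, "")[[1]]], collapse = "")
      identical(translate1(cd), translate1(tr))
    }, logical(1)))
  }
  expect_equal(conservation_index("identity"), 1)
  for (t in swinger_transformations()) {
    idx <- conservation_index(t)
    expect_equal(idx, oracle_index(t$mapping), info = t$name)
    expect_lt(idx, 1)  # no non-identity exchange conserves all codons
    expect_gte(idx, 0)
  }
  # third-position transitions are largely synonymous in the standard code
  expect_gt(conservation_index("C<>T"), conservation_index("C<>G"))
  expect_error(conservation_index("A<>T", code = c(AAA = "K")), "64 codons")
})

test_that("conservation-abundance correlation enforces the 23-class contract", {
  all_names <- names(swinger_transformations())
  idx <- vapply(all_names, conservation_index, numeric(1))
  # abundances equal to the indices correlate perfectly
  res <- conservation_abundance_correlation(setNames(idx, all_names))
  expect_equal(res$r, 1)
  expect_lt(res$p, 1e-20)
  expect_equal(res$tails, "one")
  expect_error(conservation_abundance_correlation(rep(1, 23)), "zero variance")
  expect_error(conservation_abundance_correlation(rep(1, 5)), "exactly 23")
  expect_error(
    conservation_abundance_correlation(setNames(seq_len(22), all_names[-1])),
    "23 transformations")
})

test_that("correlation p-values match the t CDF closed form", {
  withr::with_seed(51, {
    for (n in c(5, 23)) {
      x <- rnorm(n)
      y <- x + rnorm(n)
      res <- swingerseq:::correlation_result(x, y, tails = "two")
      t <- res$r * sqrt((n - 2) / (1 - res$r^2))
      expect_equal(res$p, 2 * stats::pt(-abs(t), n - 2), tolerance = 1e-6)
      one <- swingerseq:::correlation_result(x, y, tails = "one")
      expect_equal(one$p, stats::pt(t, n - 2, lower.tail = FALSE),
                   tolerance = 1e-6)
    }
  })
})
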