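#' Per-transformation class summaries
#'
#' Abundance, mean aligned length and mean percent identity for each
#' swinger class among a collection of hits.
#'
#' @param hits a hit data.frame from [batch_detect()] or
#'   [import_tabular_hits()], or any data.frame with columns naming the
#'   transformation (see `transformation_col`), `aligned_length` and
#'   `percent_identity`.
#' @param transformation_col which column identifies the class.
#' @param include_zero if `TRUE`, return rows for all 23 transformations,
#'   with abundance 0 and `NA` means for undetected classes (needed for
#'   the 23-class conservation correlation).
#' @return A data.frame with columns `transformation`, `abundance`,
#'   `mean_aligned_length`, `mean_percent_identity`.
#' @export
class_summaries <- function(hits,
                            transformation_col = "transcription_transformation",
                            include_zero = FALSE) {
  stopifnot(transformation_col %in% names(hits))
  cls <- hits[[transformation_col]]
  keep <- !is.na(cls) & cls != "identity"
  hits <- hits[keep, , drop = FALSE]
  cls <- cls[keep]
  split_idx <- split(seq_along(cls), cls)
  out <- data.frame(
    transformation = names(split_idx),
    abundance = vapply(split_idx, length, integer(1)),
    mean_aligned_length = vapply(split_idx, function(i)
      mean(hits$aligned_length[i]), numeric(1)),
    mean_percent_identity = vapply(split_idx, function(i)
      mean(hits$percent_identity[i]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (include_zero) {
    all_names <- names(transformation_set())
    missing <- setdiff(all_names, out$transformation)
    if (length(missing) > 0) {
      out <- rbind(out, data.frame(
        transformation = missing, abundance = 0L,
        mean_aligned_length = NA_real_, mean_percent_identity = NA_real_,
        stringsAsFactors = FALSE))
    }
    out <- out[match(all_names, out$transformation), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# Pearson correlation with p-value from the t transform on n - 2 df,
# t = r * sqrt((n - 2) / (1 - r^2))
correlation_result <- function(x, y, tails = c("two", "one")) {
  tails <- match.arg(tails)
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3L) stop("need at least 3 pairs (n - 2 degrees of freedom)")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  r <- stats::cor(x, y)
  df <- n - 2L
  p <- if (abs(r) >= 1) {
    0
  } else {
    t <- r * sqrt(df / (1 - r^2))
    if (tails == "two") 2 * stats::pt(-abs(t), df)
    else stats::pt(t, df, lower.tail = FALSE)  # upper tail: positive association
  }
  structure(list(r = r, p = p, tails = tails, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.4f, %s-tailed P = %.4g (n = %d)\n",
              x$r, x$tails, x$p, x$n))
  invisible(x)
}

#' Correlation of class abundance with mean aligned length
#'
#' Pearson correlation of log10 abundance against mean aligned length over
#' the classes with at least one hit, with a two-tailed p-value from the
#' t transform on n - 2 degrees of freedom. The log scale is the default
#' because class abundances span orders of magnitude; `log = FALSE` uses
#' raw abundances.
#'
#' @param summaries data.frame from [class_summaries()] (columns
#'   `abundance`, `mean_aligned_length`).
#' @param log take log10 of abundance (default).
#' @param base logarithm base (r is invariant to it; kept for
#'   explicitness).
#' @return A `correlation_result`.
#' @examples
#' s <- data.frame(abundance = c(219, 2, 1, 1, 124),
#'                 mean_aligned_length = c(325, 225, 196, 152, 308))
#' abundance_length_correlation(s)  # r = 0.96, P = 0.0094
#' @export
abundance_length_correlation <- function(summaries, log = TRUE, base = 10) {
  s <- summaries[summaries$abundance >= 1, , drop = FALSE]
  if (nrow(s) < 3L)
    stop("need at least 3 classes with abundance >= 1")
  x <- if (log) log(s$abundance, base = base) else s$abundance
  correlation_result(x, s$mean_aligned_length, tails = "two")
}

#' Exact one-tailed sign test
#'
#' Upper-tail exact binomial probability of observing at least `k`
#' successes in `n` trials at null success probability `p0`:
#' P = sum_{i = k..n} C(n, i) p0^i (1 - p0)^(n - i). Terms are summed in
#' log space, largest first, so the result is accurate to full double
#' precision even deep in the tail (no normal approximation). For the
#' thirds compartmentalization test `p0 = 2/3`, the null probability of a
#' hit falling in the mid or 3' region by chance.
#'
#' @param k observed successes.
#' @param n trials.
#' @param p0 null success probability (default 2/3).
#' @return A list of class `sign_test_result`: `k`, `n`, `p0`, `p`.
#' @examples
#' sign_test(38, 43)$p  # 0.00106
#' sign_test(33, 33)$p  # (2/3)^33 = 1.545e-6
#' @export
sign_test <- function(k, n, p0 = 2 / 3) {
  stopifnot(length(k) == 1L, length(n) == 1L, k >= 0, n >= k, p0 > 0, p0 < 1)
  k <- as.integer(k)
  n <- as.integer(n)
  if (k == 0L) {
    p <- 1
  } else {
    i <- k:n
    logterms <- lchoose(n, i) + i * log(p0) + (n - i) * log1p(-p0)
    mx <- max(logterms)
    p <- exp(mx) * sum(exp(logterms - mx))
    p <- min(p, 1)
  }
  structure(list(k = k, n = n, p0 = p0, p = p), class = "sign_test_result")
}

#' @export
print.sign_test_result <- function(x, ...) {
  cat(sprintf("<sign_test_result> k = %d of n = %d (p0 = %.4g): one-tailed P = %.4g\n",
              x$k, x$n, x$p0, x$p))
  invisible(x)
}

#' Amino-acid conservation index of a transformation
#'
#' The fraction of the 64 codons whose translation is unchanged when the
#' transformation is applied to each base of the codon. Stop is treated
#' as a 21st translation class. The identity map scores 1; no
#' non-identity exchange conserves all codons.
#'
#' @param t an `nt_transformation` or name (identity allowed).
#' @param code named character vector mapping all 64 codons to amino-acid
#'   letters (default [Biostrings::GENETIC_CODE], the standard code).
#' @return A fraction in \[0, 1\].
#' @examples
#' conservation_index("C<>T") > conservation_index("C<>G")
#' @export
conservation_index <- function(t, code = Biostrings::GENETIC_CODE) {
  t <- parse_transformation(t)
  codons <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0),
                            DNA_BASES, paste0))
  if (!all(codons %in% names(code)))
    stop("genetic code table must cover all 64 codons")
  transformed <- apply_transformation(t, codons)
  mean(unname(code[codons]) == unname(code[transformed]))
}

#' Correlation of conservation with swinger class abundance
#'
#' Pearson correlation over all 23 transformations of class abundance
#' (zero-abundance classes included) with the amino-acid conservation
#' index, with a one-tailed p-value on 21 degrees of freedom (upper tail:
#' the working hypothesis is that more conservative exchanges are more
#' abundant).
#'
#' @param abundances named numeric vector over the 23 transformations
#'   (canonical names), or a 23-long vector in enumeration order.
#' @param indices conservation indices over the same 23 classes; computed
#'   from [conservation_index()] when `NULL`.
#' @param log add-one log10 transform of abundances before correlating
#'   (`FALSE` by default: raw counts).
#' @return A `correlation_result` with `tails = "one"`.
#' @export
conservation_abundance_correlation <- function(abundances, indices = NULL,
                                               log = FALSE) {
  all_names <- names(transformation_set())
  if (!is.null(names(abundances))) {
    if (!setequal(names(abundances), all_names))
      stop("abundances must cover exactly the 23 transformations")
    abundances <- abundances[all_names]
  }
  if (length(abundances) != 23L)
    stop("need exactly 23 paired values (one per transformation)")
  if (is.null(indices))
    indices <- vapply(all_names, conservation_index, numeric(1))
  else if (length(indices) != 23L)
    stop("need exactly 23 paired values (one per transformation)")
  x <- if (log) log10(abundances + 1) else abundances
  correlation_result(as.numeric(x), as.numeric(indices), tails = "one")
}

#' Text summary of the headline statistics
#'
#' @param summaries class summaries data.frame.
#' @param mito_counts,nuclear_counts optional `list(k =, n =)` inputs for
#'   the two sign tests.
#' @return A character vector of report lines, invisibly; also printed.
#' @export
stats_report <- function(summaries, mito_counts = NULL, nuclear_counts = NULL) {
  lines <- character(0)
  al <- abundance_length_correlation(summaries)
  lines <- c(lines, sprintf(
    "abundance vs mean length (log10, %d classes): r = %.4f, two-tailed P = %.5f",
    al$n, al$r, al$p))
  for (nm in c("mito_counts", "nuclear_counts")) {
    counts <- get(nm)
    if (!is.null(counts)) {
      st <- sign_test(counts$k, counts$n)
      lines <- c(lines, sprintf(
        "%s: %d of %d in mid/3' (%.1f%%), one-tailed sign test P = %.4g",
        sub("_counts", "", nm), st$k, st$n, 100 * st$k / st$n, st$p))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
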