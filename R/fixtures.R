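#' Load the packaged swinger EST tables
#'
#' The package ships verbatim transcriptions of three published tables of
#' swinger-transformed ESTs from the FAPESP/LICR Human Cancer Genome
#' Project screen (tab-separated, one file per table, printed column
#' headers). The loader normalizes each row: transformation names are
#' canonicalized, thousands separators are stripped from coordinates,
#' spreadsheet-style scientific coordinates (e.g. "1,21E+08") are
#' expanded, chromosome labels are case-normalized (X), records printed
#' with 5' > 3' are flipped to `ref_start <= ref_end` with
#' `strand = "-"`, and a template category is assigned from the
#' chromosome and gene columns. E-values are carried as text, never
#' parsed to float.
#'
#' @param validate check the loaded tables against their documented
#'   totals (347 records; 223 symmetric / 124 asymmetric) and fail
#'   loudly, listing offending accessions, on any transcription
#'   discrepancy.
#' @return A data.frame of class `est_table` with one row per published
#'   EST record: `est_accession`, `biosample`, `tissue`, `est_length`,
#'   `transformation`, `template_accession`, `chromosome`, `gene`,
#'   `aligned_length`, `percent_identity`, `evalue`, `five_prime`,
#'   `three_prime`, `ref_start`, `ref_end`, `strand`, `source_table`,
#'   `category`.
#' @export
load_est_tables <- function(validate = TRUE) {
  files <- c(T1 = "est_table1.tsv", T2 = "est_table2.tsv", T3 = "est_table3.tsv")
  tabs <- lapply(names(files), function(tag) {
    path <- system.file("extdata", files[[tag]], package = "swingerseq",
                        mustWork = TRUE)
    raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                             colClasses = "character", encoding = "UTF-8",
                             check.names = FALSE, quote = "")
    if (ncol(raw) != 13L)
      stop("malformed fixture ", files[[tag]], ": expected 13 columns")
    names(raw) <- c("est_accession", "biosample", "tissue", "est_length",
                    "transformation", "template_accession", "chromosome",
                    "gene", "aligned_length", "percent_identity", "evalue",
                    "five_prime", "three_prime")
    raw$source_table <- tag
    raw
  })
  tab <- do.call(rbind, tabs)

  parse_coord <- function(x, what) {
    x <- trimws(x)
    # spreadsheet artifact: comma as decimal separator in scientific notation
    sci <- grepl("^[0-9]+,[0-9]+E\\+[0-9]+$", x, ignore.case = TRUE)
    x[sci] <- sub(",", ".", x[sci], fixed = TRUE)
    x[!sci] <- gsub(",", "", x[!sci], fixed = TRUE)
    out <- suppressWarnings(as.numeric(x))
    if (any(is.na(out)))
      stop("malformed fixture ", what, " in row(s): ",
           paste(which(is.na(out)), collapse = ", "))
    out
  }

  tab$est_accession <- trimws(tab$est_accession)
  bad <- !nzchar(sub("\\*$", "", tab$est_accession))
  if (any(bad)) stop("empty accession in fixture row(s): ",
                     paste(which(bad), collapse = ", "))
  tab$flagged <- grepl("\\*$", tab$est_accession)
  tab$est_accession <- sub("\\*$", "", tab$est_accession)
  tab$transformation <- vapply(tab$transformation, function(x)
    parse_transformation(x)$name, character(1), USE.NAMES = FALSE)
  tab$est_length <- as.integer(parse_coord(tab$est_length, "EST length"))
  tab$aligned_length <- as.integer(parse_coord(tab$aligned_length,
                                               "aligned length"))
  tab$percent_identity <- parse_coord(tab$percent_identity, "%ID")
  tab$five_prime <- parse_coord(tab$five_prime, "5' coordinate")
  tab$three_prime <- parse_coord(tab$three_prime, "3' coordinate")
  tab$chromosome <- toupper(trimws(tab$chromosome))
  tab$chromosome[tab$chromosome == "MITO"] <- "mito"
  tab$gene <- trimws(tab$gene)

  tab$strand <- ifelse(tab$five_prime > tab$three_prime, "-", "+")
  tab$ref_start <- pmin(tab$five_prime, tab$three_prime)
  tab$ref_end <- pmax(tab$five_prime, tab$three_prime)

  tab$category <- ifelse(
    tab$chromosome == "mito", "mitochondrial",
    ifelse(grepl("^non-coding region$", tab$gene, ignore.case = TRUE),
           "non-coding region",
           ifelse(grepl("^uncharacterized LOC", tab$gene, ignore.case = TRUE),
                  "uncharacterized", "protein-coding/known gene")))

  stopifnot(all(tab$aligned_length >= 1),
            all(tab$percent_identity > 0 & tab$percent_identity <= 100))

  if (validate) validate_est_tables(tab)
  rownames(tab) <- NULL
  class(tab) <- c("est_table", "data.frame")
  tab
}

# documented totals of the packaged transcription; any mismatch is a
# transcription error and must fail loudly with the offending accessions
validate_est_tables <- function(tab) {
  kinds <- vapply(tab$transformation, function(x)
    parse_transformation(x)$kind, character(1), USE.NAMES = FALSE)
  problems <- character(0)
  if (nrow(tab) != 347L)
    problems <- c(problems, sprintf("expected 347 records, found %d", nrow(tab)))
  if (sum(kinds == "symmetric") != 223L)
    problems <- c(problems, sprintf(
      "expected 223 symmetric records, found %d (accessions: %s)",
      sum(kinds == "symmetric"),
      paste(utils::head(tab$est_accession[kinds == "symmetric"], 5), collapse = ", ")))
  if (sum(kinds == "asymmetric") != 124L)
    problems <- c(problems, sprintf(
      "expected 124 asymmetric records, found %d (accessions: %s)",
      sum(kinds == "asymmetric"),
      paste(utils::head(tab$est_accession[kinds == "asymmetric"], 5), collapse = ", ")))
  cls <- table(tab$transformation)
  if (sum(cls) != nrow(tab))
    problems <- c(problems, "per-class counts do not sum to the total")
  if (length(problems) > 0)
    stop("fixture validation failed:\n  ", paste(problems, collapse = "\n  "))
  invisible(tab)
}

#' Summaries of the packaged EST tables
#'
#' Deterministic counts by transformation class, template category and
#' gene, reproducing the published headline numbers (347 swinger ESTs,
#' 223 symmetric, 51 mitochondrial, ...). Counts report what the tables
#' contain; the loader does not reconcile prose inconsistencies in the
#' source.
#'
#' @param records an `est_table` from [load_est_tables()].
#' @return A list of class `paper_summary`: `total`, `by_transformation`
#'   (named count vector), `n_symmetric`, `n_asymmetric`,
#'   `by_category`, `n_mitochondrial`, `mito_gene_counts`,
#'   `n_noncoding`, `n_uncharacterized`, `gene_counts` (counts of rows
#'   whose gene description mentions each parenthesized gene symbol).
#' @export
summarize_tables <- function(records = load_est_tables()) {
  kinds <- vapply(records$transformation, function(x)
    parse_transformation(x)$kind, character(1), USE.NAMES = FALSE)
  mito <- records[records$category == "mitochondrial", , drop = FALSE]
  symbols <- unlist(regmatches(records$gene,
                               gregexpr("\\(([^()]+)\\)", records$gene)))
  symbols <- gsub("[()]", "", symbols)
  structure(list(
    total = nrow(records),
    by_transformation = sort(table(records$transformation), decreasing = TRUE),
    n_symmetric = sum(kinds == "symmetric"),
    n_asymmetric = sum(kinds == "asymmetric"),
    by_category = table(records$category),
    n_mitochondrial = nrow(mito),
    mito_gene_counts = sort(table(tolower(mito$gene)), decreasing = TRUE),
    n_noncoding = sum(records$category == "non-coding region"),
    n_uncharacterized = sum(records$category == "uncharacterized"),
    gene_counts = sort(table(symbols), decreasing = TRUE)
  ), class = "paper_summary")
}

#' @export
print.paper_summary <- function(x, ...) {
  cat(sprintf("<paper_summary> %d swinger ESTs (%d symmetric, %d asymmetric)\n",
              x$total, x$n_symmetric, x$n_asymmetric))
  cat("by transformation:\n")
  print(x$by_transformation)
  cat(sprintf("mitochondrial %d | non-coding %d | uncharacterized %d\n",
              x$n_mitochondrial, x$n_noncoding, x$n_uncharacterized))
  invisible(x)
}

#' Count table records mentioning a gene symbol
#'
#' @param records an `est_table`.
#' @param symbol gene symbol (e.g. `"PABPC1"`), matched case-insensitively
#'   against the gene description; mitochondrial gene labels (e.g.
#'   `"nd2"`) are matched exactly against the gene field.
#' @return Integer count.
#' @export
count_gene_records <- function(records, symbol) {
  sum(grepl(symbol, records$gene, ignore.case = TRUE, fixed = FALSE))
}

#' Write EST table records back to TSV
#'
#' Canonical dialect: tab-separated with the normalized column names; the
#' round trip `read(write(x))` is stable.
#'
#' @param records an `est_table`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_est_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_est_table
#' @param validate passed to the same checks as [load_est_tables()].
#' @export
read_est_table <- function(path, validate = FALSE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (validate) validate_est_tables(tab)
  class(tab) <- c("est_table", "data.frame")
  tab
}
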