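#' Reference sequence collection
#'
#' @param sequences named character vector of DNA sequences (unique,
#'   non-empty names and sequences), or a `DNAStringSet`, or the path to a
#'   FASTA file.
#' @param chromosome optional character vector of chromosome labels,
#'   recycled or named like `sequences`.
#' @param class optional molecule class labels (e.g. "transcript",
#'   "genomic").
#' @return An object of class `reference_db`.
#' @export
reference_db <- function(sequences, chromosome = NULL, class = NULL) {
  seqs <- as_dna_character(sequences)
  if (length(seqs) == 0L) stop("reference database is empty")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)) ||
      any(!nzchar(names(seqs))))
    stop("reference sequences must have unique non-empty names")
  if (any(!nzchar(seqs))) stop("reference sequences must be non-empty")
  structure(list(sequences = toupper(seqs),
                 chromosome = chromosome, class = class),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db> %d sequence(s), %s nt total\n",
              length(x$sequences),
              format(sum(nchar(x$sequences)), big.mark = ",")))
  invisible(x)
}

# accept character vector, DNAStringSet or FASTA path
as_dna_character <- function(x) {
  if (inherits(x, "DNAStringSet") || inherits(x, "XStringSet"))
    return(stats::setNames(as.character(x), names(x)))
  stopifnot(is.character(x))
  if (length(x) == 1L && file.exists(x) && !dir.exists(x))
    return(read_fasta(x))
  x
}

#' Detection parameters
#'
#' Thresholds and scoring for swinger-read classification. The defaults
#' bracket the published extremes of validated hits: minimum aligned
#' length 40 nt (the smallest published hit is 41 bp) and minimum percent
#' identity 75 (the smallest published value is 75.404).
#'
#' @param min_aligned_length minimum alignment columns for a hit to pass.
#' @param min_percent_identity minimum percent identity for a hit to pass.
#' @param scoring an [sw_scoring()] scheme.
#' @param canonical_first if `TRUE` (default) the untransformed read is
#'   aligned first and a *decisive* canonical alignment (passing the
#'   thresholds and covering at least `min_canonical_coverage` of the
#'   read) short-circuits the swinger search. A canonical alignment that
#'   passes the thresholds but covers less of the read does not
#'   short-circuit; it competes by score against the 23 transformed
#'   variants, so a short spurious self-match cannot mask a near-perfect
#'   swinger explanation.
#' @param min_canonical_coverage fraction of the read the canonical
#'   alignment must span to short-circuit (default 0.5).
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(min_aligned_length = 40L,
                             min_percent_identity = 75,
                             scoring = sw_scoring(),
                             canonical_first = TRUE,
                             min_canonical_coverage = 0.5) {
  stopifnot(min_aligned_length > 0, min_percent_identity > 0,
            min_percent_identity <= 100, inherits(scoring, "sw_scoring"),
            min_canonical_coverage >= 0, min_canonical_coverage <= 1)
  structure(list(min_aligned_length = as.integer(min_aligned_length),
                 min_percent_identity = as.numeric(min_percent_identity),
                 scoring = scoring,
                 canonical_first = isTRUE(canonical_first),
                 min_canonical_coverage = min_canonical_coverage),
            class = "detection_params")
}

empty_hit <- function(read_id) {
  data.frame(
    read_id = read_id, classification = "unidentified",
    detection_transformation = NA_character_,
    transcription_transformation = NA_character_,
    reference_id = NA_character_, ref_start = NA_integer_,
    ref_end = NA_integer_, strand = NA_character_,
    query_start = NA_integer_, query_end = NA_integer_,
    aligned_length = NA_integer_, percent_identity = NA_real_,
    gap_count = NA_integer_, score = NA_integer_, ambiguous = FALSE,
    stringsAsFactors = FALSE
  )
}

# Align every transformed variant of `read` (given transformations, both
# orientations) against every reference; return the per-variant best
# alignments that pass thresholds, canonicalized to the forward strand.
scan_variants <- function(read, rc_read, transformations, db, params) {
  rows <- list()
  for (t in transformations) {
    fwd <- apply_transformation(t, read)
    rev <- apply_transformation(t, rc_read)
    # forward-strand canonical description of the reverse-orientation hit:
    # aligning t(rc(read)) is equivalent to a template-minus-strand hit
    # whose forward transformation is the complement conjugate of t.
    t_minus <- conjugate_by_complement(t)
    for (ref_id in names(db$sequences)) {
      refseq <- db$sequences[[ref_id]]
      for (orient in c("+", "-")) {
        variant <- if (orient == "+") fwd else rev
        al <- sw_window_align(variant, refseq, params$scoring)
        if (al$aligned_length == 0) next
        pid <- 100 * al$matches / al$aligned_length
        if (al$aligned_length < params$min_aligned_length ||
            pid < params$min_percent_identity) next
        t_report <- if (orient == "+") t else t_minus
        rows[[length(rows) + 1L]] <- data.frame(
          detection_transformation = t_report$name,
          reference_id = ref_id, ref_start = al$ref_start,
          ref_end = al$ref_end, strand = orient,
          query_start = al$query_start, query_end = al$query_end,
          aligned_length = al$aligned_length,
          percent_identity = pid, gap_count = al$gap_count,
          score = al$score,
          support = if (is_identity(t_report)) 0L
                    else transformation_support(t_report),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

# deterministic best-candidate choice: score desc, then smaller
# transformation support, then canonical name, then reference order,
# smaller ref_start, smaller query_start, shorter alignment
pick_best <- function(cand, db) {
  ord <- order(-cand$score, cand$support,
               rank_c_locale(cand$detection_transformation),
               match(cand$reference_id, names(db$sequences)),
               cand$ref_start, cand$query_start, cand$aligned_length)
  cand <- cand[ord, , drop = FALSE]
  best <- cand[1L, , drop = FALSE]
  ties <- cand$score == best$score &
    cand$detection_transformation != best$detection_transformation
  best$ambiguous <- any(ties)
  best
}

rank_c_locale <- function(x) match(x, sort_c_locale(unique(x)))

sort_c_locale <- function(x) {
  prev <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", prev)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  sort(x)
}

#' Classify one read as canonical, swinger or unidentified
#'
#' The read is aligned locally against every reference sequence, in both
#' orientations. With `canonical_first` the untransformed read is tried
#' first; a decisive canonical alignment (thresholds passed, read
#' coverage at least `min_canonical_coverage`) classifies the read as
#' canonical without testing exchanges. Otherwise all 23 transformed
#' variants are aligned (any weak canonical candidate competes among
#' them by score) and the best passing alignment defines the hit.
#'
#' `detection_transformation` is the exchange applied to the read that
#' produced the alignment, canonicalized to the forward strand of the
#' template: a hit found in reverse orientation is re-expressed through
#' the complement conjugate and reported with `strand = "-"`.
#' `transcription_transformation` is its inverse -- the exchange the
#' polymerase would have performed reading the template.
#'
#' @param read a DNA string.
#' @param db a [reference_db()].
#' @param params a [detection_params()].
#' @param read_id identifier used in the returned row.
#' @return A one-row data.frame (see [batch_detect()] for columns).
#' @export
detect_swinger <- function(read, db, params = detection_params(),
                           read_id = "read") {
  stopifnot(inherits(db, "reference_db"), inherits(params, "detection_params"))
  if (!is.character(read) || length(read) != 1L || !nzchar(read))
    stop("read must be a non-empty DNA string")
  read <- apply_transformation(identity_transformation(), read)  # validate + normalize
  rc_read <- reverse_complement(read)

  ident <- list(identity_transformation())
  swingers <- transformation_set()

  canonical_cand <- NULL
  if (params$canonical_first) {
    canonical_cand <- scan_variants(read, rc_read, ident, db, params)
    if (!is.null(canonical_cand)) {
      best <- pick_best(canonical_cand, db)
      span <- best$query_end - best$query_start + 1L
      if (span >= params$min_canonical_coverage * nchar(read))
        return(finish_hit(best, read_id, "canonical"))
    }
    cand <- rbind(canonical_cand,
                  scan_variants(read, rc_read, swingers, db, params))
  } else {
    cand <- scan_variants(read, rc_read, c(ident, swingers), db, params)
  }
  if (is.null(cand)) return(empty_hit(read_id))
  best <- pick_best(cand, db)
  cls <- if (best$support == 0L) "canonical" else "swinger"
  finish_hit(best, read_id, cls)
}

finish_hit <- function(best, read_id, classification) {
  det <- best$detection_transformation
  trans <- if (det == "identity") "identity"
           else invert_transformation(det)$name
  data.frame(
    read_id = read_id, classification = classification,
    detection_transformation = det, transcription_transformation = trans,
    reference_id = best$reference_id, ref_start = best$ref_start,
    ref_end = best$ref_end, strand = best$strand,
    query_start = best$query_start, query_end = best$query_end,
    aligned_length = best$aligned_length,
    percent_identity = best$percent_identity, gap_count = best$gap_count,
    score = best$score, ambiguous = best$ambiguous,
    stringsAsFactors = FALSE
  )
}

#' Classify a batch of reads
#'
#' Applies [detect_swinger()] to every read, preserving input order, and
#' logs a one-line per-classification count summary to standard error.
#'
#' @param reads named character vector of reads, a `DNAStringSet`, or a
#'   FASTA path.
#' @param db a [reference_db()].
#' @param params a [detection_params()].
#' @param quiet suppress the summary log line.
#' @return A data.frame with one row per read and columns `read_id`,
#'   `classification`, `detection_transformation`,
#'   `transcription_transformation`, `reference_id`, `ref_start`,
#'   `ref_end`, `strand`, `query_start`, `query_end`, `aligned_length`,
#'   `percent_identity`, `gap_count`, `score`, `ambiguous`.
#' @export
batch_detect <- function(reads, db, params = detection_params(),
                         quiet = FALSE) {
  reads <- as_dna_character(reads)
  if (length(reads) == 0L) {
    out <- empty_hit("x")[0L, , drop = FALSE]
    if (!quiet) message("batch_detect: 0 reads")
    return(out)
  }
  if (is.null(names(reads)))
    names(reads) <- paste0("read", seq_along(reads))
  rows <- lapply(seq_along(reads), function(i)
    detect_swinger(reads[[i]], db, params, read_id = names(reads)[i]))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!quiet) {
    counts <- table(factor(out$classification,
                           levels = c("canonical", "swinger", "unidentified")))
    message(sprintf(
      "batch_detect: %d reads | canonical %d, swinger %d, unidentified %d",
      nrow(out), counts[["canonical"]], counts[["swinger"]],
      counts[["unidentified"]]))
  }
  out
}

#' Write or read a hit table as TSV
#'
#' @param hits data.frame of hits from [batch_detect()].
#' @param path file path.
#' @return `write_hits` returns the path invisibly; `read_hits` the
#'   data.frame.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}

#' Import externally produced tabular hits
#'
#' Reads a 12-column BLAST-outfmt-6-like file (query, subject, percent
#' identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, evalue, bitscore) with an additional 13th column naming
#' the transformation applied to the query before the search, and maps it
#' onto the package's hit columns. Subject coordinates with start > end
#' are normalized to `strand = "-"`.
#'
#' @param path path to the tabular file (no header).
#' @return A hit data.frame (the `score` column carries the bitscore;
#'   `gap_count` the reported gap opens; e-values are not retained).
#' @export
import_tabular_hits <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 13L)
    stop("expected 13 columns: 12 tabular hit columns + transformation")
  names(tab)[1:13] <- c("query", "subject", "pident", "length", "mismatch",
                        "gapopen", "qstart", "qend", "sstart", "send",
                        "evalue", "bitscore", "transformation")
  minus <- tab$sstart > tab$send
  det <- vapply(tab$transformation, function(x) parse_transformation(x)$name,
                character(1), USE.NAMES = FALSE)
  data.frame(
    read_id = tab$query,
    classification = ifelse(det == "identity", "canonical", "swinger"),
    detection_transformation = det,
    transcription_transformation = vapply(det, function(x)
      if (x == "identity") "identity" else invert_transformation(x)$name,
      character(1), USE.NAMES = FALSE),
    reference_id = tab$subject,
    ref_start = as.integer(pmin(tab$sstart, tab$send)),
    ref_end = as.integer(pmax(tab$sstart, tab$send)),
    strand = ifelse(minus, "-", "+"),
    query_start = as.integer(tab$qstart), query_end = as.integer(tab$qend),
    aligned_length = as.integer(tab$length),
    percent_identity = as.numeric(tab$pident),
    gap_count = as.integer(tab$gapopen),
    score = as.numeric(tab$bitscore), ambiguous = FALSE,
    stringsAsFactors = FALSE
  )
}
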