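#' Simulation configuration
#'
#' Defaults emulate the EST regime the detector targets: one 100 kb
#' random reference at human-like GC (0.41), reads of 100-600 nt, a
#' strongly skewed class distribution with one dominant symmetric class
#' (A<>T) and one dominant asymmetric class (A->T->C->G->A) mirroring the
#' published 219/124 dominance (preset `"paper-like"`), substitution-only
#' noise, and equal forward/reverse orientation.
#'
#' @param n_reference number of reference sequences.
#' @param reference_length length of each reference (nt), recycled.
#' @param gc GC fraction of the i.i.d. reference bases.
#' @param n_reads number of planted reads.
#' @param read_length_range integer range (min, max) of read lengths.
#' @param class_probs named probability vector over `"identity"` and the
#'   23 canonical transformation names (missing classes get probability
#'   0), or the string `"paper-like"` for the published class skew with
#'   no canonical reads.
#' @param noise_rate per-base substitution probability applied to reads.
#' @param revcomp_prob probability that a read is planted on the minus
#'   strand.
#' @param seed integer random seed; runs are bit-reproducible under it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_reference = 1L, reference_length = 100000L,
                              gc = 0.41, n_reads = 100L,
                              read_length_range = c(100L, 600L),
                              class_probs = "paper-like",
                              noise_rate = 0, revcomp_prob = 0.5,
                              seed = 1L) {
  if (identical(class_probs, "paper-like")) {
    class_probs <- c(219, 2, 1, 1, 124) / 347
    names(class_probs) <- c("A<>T", "A<>C", "C<>T", "G<>T", "A-T-C-G-A")
  }
  names(class_probs) <- vapply(names(class_probs), function(x)
    parse_transformation(x)$name, character(1), USE.NAMES = FALSE)
  stopifnot(
    n_reference >= 1, all(reference_length >= 1),
    gc >= 0, gc <= 1, n_reads >= 0,
    length(read_length_range) == 2L,
    read_length_range[1L] >= 1,
    read_length_range[2L] >= read_length_range[1L],
    abs(sum(class_probs) - 1) < 1e-8, all(class_probs >= 0),
    noise_rate >= 0, noise_rate <= 1,
    revcomp_prob >= 0, revcomp_prob <= 1
  )
  structure(list(
    n_reference = as.integer(n_reference),
    reference_length = as.integer(rep_len(reference_length, n_reference)),
    gc = gc, n_reads = as.integer(n_reads),
    read_length_range = as.integer(read_length_range),
    class_probs = class_probs, noise_rate = noise_rate,
    revcomp_prob = revcomp_prob, seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Generate random reference sequences
#'
#' i.i.d. bases with the configured GC fraction (G and C equiprobable
#' within GC, likewise A and T). Deterministic under the config seed.
#'
#' @param config a [simulation_config()].
#' @return Named character vector (`ref1`, `ref2`, ...).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (any(config$reference_length <= 0)) stop("reference length must be positive")
  withr_seed(config$seed, {
    probs <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
               G = config$gc / 2, T = (1 - config$gc) / 2)
    seqs <- vapply(config$reference_length, function(len) {
      paste(sample(DNA_BASES, len, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
    stats::setNames(seqs, paste0("ref", seq_along(seqs)))
  })
}

# run expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Plant transformed reads in a reference
#'
#' Each read is a fragment of a reference: optionally reverse-complemented
#' (the template is then the minus strand), transformed by a class drawn
#' from the configured distribution, and substitution-noised. The truth
#' table records everything needed to reconstruct the read.
#'
#' @param reference named character vector of references (or a
#'   [generate_reference()] result).
#' @param config a [simulation_config()].
#' @return A list with elements `reads` (named character vector) and
#'   `truth` (data.frame: `read_id`, `reference_id`, `ref_start`,
#'   `ref_end`, `strand`, `transformation` (canonical name or
#'   `"identity"`), `n_substitutions`, `read_length`).
#' @export
plant_reads <- function(reference, config) {
  stopifnot(inherits(config, "simulation_config"))
  reference <- as_dna_character(reference)
  if (length(reference) == 0L || any(!nzchar(reference)))
    stop("reference must be non-empty")
  if (config$read_length_range[2L] > max(nchar(reference)))
    stop("read length exceeds reference length")
  withr_seed(config$seed + 1L, {
    n <- config$n_reads
    classes <- names(config$class_probs)
    reads <- character(n)
    truth <- vector("list", n)
    lens <- config$read_length_range[1L]:config$read_length_range[2L]
    for (i in seq_len(n)) {
      len <- lens[sample.int(length(lens), 1L)]
      eligible <- which(nchar(reference) >= len)
      ref_i <- eligible[sample.int(length(eligible), 1L)]
      start <- sample.int(nchar(reference[[ref_i]]) - len + 1L, 1L)
      frag <- substr(reference[[ref_i]], start, start + len - 1L)
      minus <- stats::runif(1) < config$revcomp_prob
      template <- if (minus) reverse_complement(frag) else frag
      t_name <- sample(classes, 1L, prob = config$class_probs)
      read <- apply_transformation(t_name, template)
      nsub <- 0L
      if (config$noise_rate > 0) {
        pos <- which(stats::runif(len) < config$noise_rate)
        nsub <- length(pos)
        if (nsub > 0L) {
          chars <- strsplit(read, "")[[1L]]
          for (p in pos) {
            chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
          }
          read <- paste(chars, collapse = "")
        }
      }
      reads[i] <- read
      truth[[i]] <- data.frame(
        read_id = sprintf("sim%04d", i),
        reference_id = names(reference)[ref_i],
        ref_start = start, ref_end = start + len - 1L,
        strand = if (minus) "-" else "+",
        transformation = t_name, n_substitutions = nsub,
        read_length = len, stringsAsFactors = FALSE
      )
    }
    truth <- do.call(rbind, truth)
    names(reads) <- truth$read_id
    list(reads = reads, truth = truth)
  })
}

#' Write a simulated data set to disk
#'
#' Writes `<prefix>.ref.fasta`, `<prefix>.reads.fasta` and
#' `<prefix>.truth.tsv`.
#'
#' @param config a [simulation_config()].
#' @param prefix output path prefix.
#' @return Invisibly, the list returned by [plant_reads()] plus the
#'   reference.
#' @export
simulate_dataset <- function(config, prefix = NULL) {
  ref <- generate_reference(config)
  planted <- plant_reads(ref, config)
  if (!is.null(prefix)) {
    write_fasta(ref, paste0(prefix, ".ref.fasta"))
    write_fasta(planted$reads, paste0(prefix, ".reads.fasta"))
    utils::write.table(planted$truth, paste0(prefix, ".truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  invisible(c(list(reference = ref), planted))
}

#' Evaluate detection against planted truth
#'
#' Compares detector output with the simulator's truth table: the
#' predicted class of a read is its `transcription_transformation`
#' (`"identity"` for canonical calls, `"unidentified"` when nothing
#' passed), which for planted reads equals the exchange applied when the
#' read was generated, on either strand.
#'
#' @param truth truth data.frame from [plant_reads()] (or its TSV path).
#' @param hits hit data.frame from [batch_detect()] (or its TSV path).
#' @param min_overlap fraction of the truth interval a hit must overlap
#'   (same reference) to count as locus-correct.
#' @return A list of class `detection_evaluation`: `confusion` (25 x 25
#'   table: identity + 23 classes + unidentified), `per_class`
#'   (data.frame of precision/recall per true class), `class_accuracy`,
#'   `locus_accuracy`.
#' @export
evaluate_detection <- function(truth, hits, min_overlap = 0.9) {
  if (is.character(truth)) truth <- utils::read.delim(truth, stringsAsFactors = FALSE)
  if (is.character(hits)) hits <- read_hits(hits)
  orphans <- c(setdiff(truth$read_id, hits$read_id),
               setdiff(hits$read_id, truth$read_id))
  if (length(orphans) > 0)
    stop("read ids do not match; orphans: ", paste(orphans, collapse = ", "))
  hits <- hits[match(truth$read_id, hits$read_id), , drop = FALSE]

  levels_all <- c("identity", names(transformation_set()), "unidentified")
  truth_cls <- factor(truth$transformation, levels = levels_all)
  pred_raw <- ifelse(hits$classification == "unidentified", "unidentified",
                     hits$transcription_transformation)
  pred_cls <- factor(pred_raw, levels = levels_all)
  confusion <- table(truth = truth_cls, predicted = pred_cls)

  per_class <- do.call(rbind, lapply(levels_all, function(cl) {
    tp <- sum(truth_cls == cl & pred_cls == cl)
    fn <- sum(truth_cls == cl & pred_cls != cl)
    fp <- sum(truth_cls != cl & pred_cls == cl)
    data.frame(class = cl, n_true = tp + fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  per_class <- per_class[per_class$n_true > 0 | !is.na(per_class$precision), ,
                         drop = FALSE]

  aligned <- !is.na(hits$ref_start)
  ov <- rep(FALSE, nrow(hits))
  same_ref <- aligned & hits$reference_id == truth$reference_id
  ovlen <- pmin(hits$ref_end, truth$ref_end) - pmax(hits$ref_start, truth$ref_start) + 1
  ov[same_ref] <- (ovlen[same_ref] / truth$read_length[same_ref]) >= min_overlap

  structure(list(
    confusion = confusion,
    per_class = per_class,
    class_accuracy = mean(as.character(truth_cls) == as.character(pred_cls)),
    locus_accuracy = if (any(aligned)) mean(ov[aligned]) else NA_real_
  ), class = "detection_evaluation")
}

#' @export
print.detection_evaluation <- function(x, ...) {
  cat(sprintf("<detection_evaluation> class accuracy %.3f | locus accuracy %.3f\n",
              x$class_accuracy, x$locus_accuracy))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}
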