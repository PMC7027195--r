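#' Gene models from BED12
#'
#' Reads transcript/gene models from a BED12 file (0-based half-open, per
#' the standard) via [rtracklayer::import()] and converts them to the
#' package's 1-based inclusive convention. Exon intervals come from the
#' block columns; the transcript length is the sum of exon widths.
#'
#' @param path BED12 file path.
#' @param category optional per-model category labels (recycled), one of
#'   `"protein-coding"`, `"non-coding RNA gene"`, `"uncharacterized"`,
#'   `"mitochondrial"`.
#' @return A list of class `gene_model_set`; each element is a
#'   `gene_model` list with `gene`, `chromosome`, `strand`, `start`,
#'   `end`, `exons` (two-column matrix, 1-based inclusive, sorted) and
#'   `transcript_length`.
#' @export
read_gene_models <- function(path, category = "protein-coding") {
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- S4Vectors::mcols(gr)$blocks
  category <- rep_len(category, length(gr))
  models <- lapply(seq_along(gr), function(i) {
    g_start <- GenomicRanges::start(gr)[i]
    g_end <- GenomicRanges::end(gr)[i]
    if (!is.null(blocks) && !is.null(blocks[[i]]) && length(blocks[[i]]) > 0) {
      ex_rel <- blocks[[i]]  # IRanges relative to the chrom start of the model
      exons <- cbind(start = g_start + IRanges::start(ex_rel) - 1L,
                     end = g_start + IRanges::end(ex_rel) - 1L)
    } else {
      exons <- cbind(start = g_start, end = g_end)
    }
    gene_model(
      gene = S4Vectors::mcols(gr)$name[i],
      chromosome = as.character(GenomicRanges::seqnames(gr)[i]),
      strand = as.character(GenomicRanges::strand(gr)[i]),
      start = g_start, end = g_end, exons = exons,
      category = category[i]
    )
  })
  names(models) <- vapply(models, `[[`, character(1), "gene")
  structure(models, class = "gene_model_set")
}

#' Construct a gene model
#'
#' @param gene gene identifier.
#' @param chromosome chromosome label.
#' @param strand `"+"` or `"-"` (or `"*"` when unknown).
#' @param start,end genomic span, 1-based inclusive.
#' @param exons two-column matrix of exon `start`/`end` coordinates
#'   (1-based inclusive, non-overlapping); defaults to the whole span.
#' @param category model category label.
#' @return A list of class `gene_model`.
#' @export
gene_model <- function(gene, chromosome = NA_character_, strand = "+",
                       start, end, exons = NULL,
                       category = "protein-coding") {
  stopifnot(start >= 1, end >= start)
  if (is.null(exons)) exons <- cbind(start = start, end = end)
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 1L] > exons[, 2L]) || any(exons[, 1L] < start) ||
      any(exons[, 2L] > end))
    stop("exons must lie within the gene span with start <= end")
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] <= exons[-nrow(exons), 2L]))
    stop("exons must be non-overlapping")
  structure(list(gene = gene, chromosome = chromosome, strand = strand,
                 start = as.integer(start), end = as.integer(end),
                 exons = exons,
                 transcript_length =
                   as.integer(sum(exons[, 2L] - exons[, 1L] + 1L)),
                 category = category),
            class = "gene_model")
}

#' Assign a hit to the 5', mid or 3' third of a gene
#'
#' Genes are compartmentalized into three equal regions; a hit belongs to
#' the region containing its midpoint. Coordinates must already be
#' expressed in the 5'-to-3' direction of the gene (1-based transcript or
#' span coordinates). With `m = floor((start + end) / 2)`, the hit is
#' `five_prime` when `m <= floor(L/3)`, `mid` when `m <= floor(2L/3)`,
#' otherwise `three_prime` (boundary positions belong to the earlier
#' region).
#'
#' @param hit_start,hit_end hit interval in gene coordinates (vectors).
#' @param L gene (transcript) length in nt.
#' @return A data.frame with columns `third` (factor with levels
#'   `five_prime`, `mid`, `three_prime`) and `midpoint`.
#' @examples
#' assign_third(1485, 1803, 3600)$third  # mid
#' @export
assign_third <- function(hit_start, hit_end, L) {
  n <- max(length(hit_start), length(hit_end), length(L))
  hit_start <- rep_len(as.numeric(hit_start), n)
  hit_end <- rep_len(as.numeric(hit_end), n)
  L <- rep_len(as.numeric(L), n)
  if (any(hit_start < 1 | hit_end < hit_start | hit_end > L))
    stop("hit interval must satisfy 1 <= start <= end <= L")
  m <- floor((hit_start + hit_end) / 2)
  third <- ifelse(m <= floor(L / 3), "five_prime",
                  ifelse(m <= floor(2 * L / 3), "mid", "three_prime"))
  data.frame(third = factor(third,
                            levels = c("five_prime", "mid", "three_prime")),
             midpoint = as.integer(m))
}

#' Exon/intron structure of a hit
#'
#' Classifies a genomic hit interval against a gene model: `exonic` when
#' fully covered by exons, `intronic` when inside the gene span but
#' disjoint from every exon, `spanning` when it overlaps both exon and
#' intron (or an exon boundary into intergenic flank is absent --
#' spanning refers to exon/intron mixtures within the span), `intergenic`
#' when outside the span. The four classes are exhaustive and mutually
#' exclusive.
#'
#' @param hit_start,hit_end genomic interval (1-based inclusive).
#' @param model a [gene_model()].
#' @return A character scalar.
#' @export
classify_structure <- function(hit_start, hit_end, model) {
  stopifnot(inherits(model, "gene_model"), hit_start <= hit_end)
  if (hit_end < model$start || hit_start > model$end) return("intergenic")
  ex <- model$exons
  ov <- pmin(hit_end, ex[, 2L]) - pmax(hit_start, ex[, 1L]) + 1L
  exon_overlap <- sum(pmax(ov, 0L))
  len_inside <- min(hit_end, model$end) - max(hit_start, model$start) + 1L
  hit_len <- hit_end - hit_start + 1L
  if (exon_overlap == hit_len) return("exonic")
  if (exon_overlap == 0L && len_inside == hit_len) return("intronic")
  "spanning"
}

#' Count hits mapping to the mid or 3' region
#'
#' The input to the one-tailed sign test: of `n` region assignments, how
#' many fall in the mid or 3' third.
#'
#' @param thirds a factor/character vector of region labels, or the
#'   data.frame returned by [assign_third()].
#' @return A list with elements `k` (mid + 3' count) and `n` (total).
#' @export
mid_or_three_counts <- function(thirds) {
  if (is.data.frame(thirds)) thirds <- thirds$third
  thirds <- as.character(thirds)
  bad <- setdiff(unique(thirds), c("five_prime", "mid", "three_prime"))
  if (length(bad) > 0) stop("unknown region label: ", paste(bad, collapse = ", "))
  list(k = sum(thirds %in% c("mid", "three_prime")), n = length(thirds))
}

#' Annotate detection hits with gene-model context
#'
#' Joins hits to gene models by `reference_id` (transcript-mode: the hit's
#' reference IS the modelled transcript) or by chromosome overlap
#' (genomic mode). Thirds are computed on the transcript length when the
#' reference is a transcript, else on the genomic span, with coordinates
#' flipped to the 5'-to-3' direction of minus-strand genes before the
#' thirds rule is applied.
#'
#' @param hits hit data.frame from [batch_detect()].
#' @param models a `gene_model_set` (or list of [gene_model()]s) named by
#'   reference/gene id.
#' @return `hits` with added columns `third`, `structure_class` and
#'   `template_category` (`NA` where no model matches).
#' @export
annotate_hits <- function(hits, models) {
  hits$third <- NA_character_
  hits$structure_class <- NA_character_
  hits$template_category <- NA_character_
  for (i in seq_len(nrow(hits))) {
    if (is.na(hits$reference_id[i])) next
    model <- models[[hits$reference_id[i]]]
    if (is.null(model)) next
    s <- hits$ref_start[i]
    e <- hits$ref_end[i]
    hits$structure_class[i] <- classify_structure(s, e, model)
    # gene-direction coordinates relative to the span
    L <- model$end - model$start + 1L
    rs <- s - model$start + 1L
    re <- e - model$start + 1L
    if (identical(model$strand, "-")) {
      tmp <- rs
      rs <- L - re + 1L
      re <- L - tmp + 1L
    }
    rs <- max(1L, rs)
    re <- min(L, re)
    if (rs <= re)
      hits$third[i] <- as.character(assign_third(rs, re, L)$third)
    hits$template_category[i] <- model$category
  }
  hits
}
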