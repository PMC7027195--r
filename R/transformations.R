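#' @useDynLib swingerseq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DNA_BASES <- c("A", "C", "G", "T")
ARROW_SWAP <- "\u2194"   # <-> glyph used in canonical names, e.g. A↔T
ARROW_CYCLE <- "\u2192"  # -> glyph used in cycle names, e.g. A→T→C→G→A

#' Construct a nucleotide transformation object
#'
#' A swinger transformation is a non-identity bijection of the DNA alphabet
#' \{A, C, G, T\}, applied uniformly along a sequence. Exactly 23 exist:
#' 9 symmetric (involutions: 6 single swaps, 3 double swaps) and 14
#' asymmetric (directional cycles: 8 three-cycles and 6 four-cycles).
#'
#' @param mapping named character vector giving the image of each of
#'   A, C, G, T under the bijection.
#' @return An object of class `nt_transformation` with elements `name`
#'   (canonical display string), `mapping`, `kind` (`"symmetric"`,
#'   `"asymmetric"` or `"identity"`) and `cycle_type`.
#' @keywords internal
new_transformation <- function(mapping) {
  mapping <- mapping[DNA_BASES]
  stopifnot(identical(sort(unname(mapping)), DNA_BASES))
  cyc <- cycle_decomposition(mapping)
  structure(
    list(
      name = canonical_name(cyc),
      mapping = mapping,
      kind = transformation_kind(cyc),
      cycle_type = cycle_type_label(cyc)
    ),
    class = "nt_transformation"
  )
}

# cycles of the permutation as a list of character vectors, fixed points dropped
cycle_decomposition <- function(mapping) {
  seen <- character(0)
  cycles <- list()
  for (b in DNA_BASES) {
    if (b %in% seen) next
    cyc <- b
    nxt <- unname(mapping[[b]])
    while (nxt != b) {
      cyc <- c(cyc, nxt)
      nxt <- unname(mapping[[nxt]])
    }
    seen <- c(seen, cyc)
    if (length(cyc) > 1L) cycles[[length(cycles) + 1L]] <- cyc
  }
  cycles
}

# Canonical naming: single swaps "X<->Y" with X < Y; double swaps
# "X<->Y+Z<->W" with each pair sorted and pairs ordered by first base;
# cycles written starting from the alphabetically first moved base and
# closed on that base, e.g. "A->T->C->G->A".
canonical_name <- function(cycles) {
  if (length(cycles) == 0L) return("identity")
  lens <- vapply(cycles, length, integer(1))
  if (all(lens == 2L)) {
    pairs <- lapply(cycles, sort)
    pairs <- pairs[order(vapply(pairs, `[`, character(1), 1L))]
    return(paste(
      vapply(pairs, function(p) paste0(p[1L], ARROW_SWAP, p[2L]), character(1)),
      collapse = "+"
    ))
  }
  cyc <- cycles[[1L]]
  start <- which.min(match(cyc, DNA_BASES))
  cyc <- c(cyc[start:length(cyc)], cyc[seq_len(start - 1L)])
  paste(c(cyc, cyc[1L]), collapse = ARROW_CYCLE)
}

transformation_kind <- function(cycles) {
  if (length(cycles) == 0L) return("identity")
  if (all(vapply(cycles, length, integer(1)) == 2L)) "symmetric" else "asymmetric"
}

cycle_type_label <- function(cycles) {
  lens <- sort(vapply(cycles, length, integer(1)))
  if (length(lens) == 0L) return("identity")
  if (identical(lens, 2L)) return("2-cycle")
  if (identical(lens, c(2L, 2L))) return("2+2-cycle")
  if (identical(lens, 3L)) return("3-cycle")
  "4-cycle"
}

#' @export
print.nt_transformation <- function(x, ...) {
  cat(sprintf("<nt_transformation> %s (%s, %s)\n", x$name, x$kind, x$cycle_type))
  cat(sprintf("  A>%s  C>%s  G>%s  T>%s\n",
              x$mapping[["A"]], x$mapping[["C"]], x$mapping[["G"]],
              x$mapping[["T"]]))
  invisible(x)
}

#' @export
format.nt_transformation <- function(x, ...) x$name

# all 4! = 24 permutations of the four bases, as a list of named vectors
all_base_permutations <- function() {
  perms <- list()
  for (a in 1:4) for (b in 1:4) for (g in 1:4) for (t in 1:4) {
    idx <- c(a, b, g, t)
    if (length(unique(idx)) == 4L) {
      perms[[length(perms) + 1L]] <-
        stats::setNames(DNA_BASES[idx], DNA_BASES)
    }
  }
  perms
}

#' The identity transformation
#'
#' Returned by [compose_transformations()] when two transformations cancel,
#' and used as the `detection_transformation` of canonical hits.
#'
#' @return An `nt_transformation` with `kind = "identity"`.
#' @export
identity_transformation <- function() {
  mapping <- stats::setNames(DNA_BASES, DNA_BASES)
  structure(
    list(name = "identity", mapping = mapping, kind = "identity",
         cycle_type = "identity"),
    class = "nt_transformation"
  )
}

is_identity <- function(t) all(t$mapping == DNA_BASES)

#' Enumerate the 23 swinger transformations
#'
#' Returns every non-identity bijection of \{A, C, G, T\} exactly once, in a
#' stable order: the 9 symmetric transformations first, then the 14
#' asymmetric ones, each group sorted lexicographically by canonical name
#' (byte order, locale independent).
#'
#' @return A named list of 23 `nt_transformation` objects, named by their
#'   canonical display strings.
#' @examples
#' tr <- swinger_transformations()
#' length(tr)                       # 23
#' table(vapply(tr, `[[`, "", "kind"))
#' @export
swinger_transformations <- function() {
  perms <- all_base_permutations()
  tr <- lapply(perms, new_transformation)
  tr <- Filter(function(t) t$kind != "identity", tr)
  names(tr) <- vapply(tr, `[[`, character(1), "name")
  sym <- vapply(tr, `[[`, character(1), "kind") == "symmetric"
  byte_order <- function(x) {
    prev <- Sys.getlocale("LC_COLLATE")
    on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", prev)), add = TRUE)
    suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
    order(x)
  }
  c(tr[sym][byte_order(names(tr)[sym])],
    tr[!sym][byte_order(names(tr)[!sym])])
}

# cache: enumeration is pure and called in inner loops
the <- new.env(parent = emptyenv())
transformation_set <- function() {
  if (is.null(the$transformations)) the$transformations <- swinger_transformations()
  the$transformations
}

#' Parse a transformation name
#'
#' Accepts canonical names with arrow glyphs (`"A↔T"`,
#' `"A→T→C→G→A"`), ASCII aliases (`"A<>T"`,
#' `"A<>T+C<>G"`, `"A-T-C-G-A"`) and arbitrary internal whitespace, as found
#' in published tables. The canonical object is always returned, so parsing
#' a canonical name round-trips.
#'
#' @param x character scalar naming a transformation, or an
#'   `nt_transformation` (returned unchanged).
#' @return An `nt_transformation`.
#' @examples
#' parse_transformation("A <> T")$name
#' parse_transformation("A-G-T-A")$cycle_type
#' @export
parse_transformation <- function(x) {
  if (inherits(x, "nt_transformation")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  s <- gsub("\\s+", "", x)
  if (s == "identity") return(identity_transformation())
  s <- gsub("<>", ARROW_SWAP, s, fixed = TRUE)
  s <- gsub("->", ARROW_CYCLE, s, fixed = TRUE)
  mapping <- stats::setNames(DNA_BASES, DNA_BASES)
  if (grepl(ARROW_SWAP, s, fixed = TRUE)) {
    for (part in strsplit(s, "+", fixed = TRUE)[[1L]]) {
      pair <- strsplit(part, ARROW_SWAP, fixed = TRUE)[[1L]]
      if (length(pair) != 2L || !all(pair %in% DNA_BASES))
        stop("cannot parse transformation name: ", sQuote(x))
      mapping[pair] <- rev(pair)
    }
  } else {
    cyc <- strsplit(gsub("-", ARROW_CYCLE, s), ARROW_CYCLE, fixed = TRUE)[[1L]]
    n <- length(cyc)
    if (n < 4L || cyc[1L] != cyc[n] || !all(cyc %in% DNA_BASES) ||
        anyDuplicated(cyc[-n]))
      stop("cannot parse transformation name: ", sQuote(x))
    for (i in seq_len(n - 1L)) mapping[cyc[i]] <- cyc[i + 1L]
  }
  if (all(mapping == DNA_BASES)) return(identity_transformation())
  new_transformation(mapping)
}

#' Apply a transformation to DNA sequences
#'
#' Replaces every A, C, G and T according to the bijection. IUPAC ambiguity
#' codes are mapped to the code whose base set is the image of their base
#' set (so the transformation commutes with ambiguity semantics); N is
#' therefore fixed. U is normalized to T on input, lowercase is uppercased,
#' and output is always uppercase DNA.
#'
#' @param t an `nt_transformation` or a name accepted by
#'   [parse_transformation()].
#' @param x character vector of sequences (IUPAC alphabet).
#' @return Character vector of transformed sequences, same lengths as input.
#' @examples
#' apply_transformation("A<>T", "GATTACA")   # "GTAATCT"
#' apply_transformation("A-T-C-G-A", "ACGT") # "TGAC"
#' @export
apply_transformation <- function(t, x) {
  t <- parse_transformation(t)
  stopifnot(is.character(x))
  up <- chartr("u", "U", toupper(x))
  up <- chartr("U", "T", up)
  bad <- regexpr(paste0("[^", paste(iupac_alphabet(), collapse = ""), "]"), up)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid character %s at position %d of sequence %d",
                 sQuote(substr(up[i], bad[i], bad[i])), bad[i], i))
  }
  tab <- iupac_image_table(t)
  chartr(paste(names(tab), collapse = ""), paste(tab, collapse = ""), up)
}

iupac_alphabet <- function() names(Biostrings::IUPAC_CODE_MAP)

# image of every IUPAC code under t: the code whose base set is the image
# of the code's base set
iupac_image_table <- function(t) {
  code_map <- Biostrings::IUPAC_CODE_MAP
  key <- function(bases) paste(sort(bases), collapse = "")
  by_set <- stats::setNames(names(code_map),
                            vapply(strsplit(code_map, ""), key, character(1)))
  images <- vapply(strsplit(code_map, ""), function(bases) {
    by_set[[key(unname(t$mapping[bases]))]]
  }, character(1))
  stats::setNames(images, names(code_map))
}

#' Invert a transformation
#'
#' Symmetric transformations are involutions and are their own inverse; an
#' asymmetric cycle inverts to the reversed cycle. Template assignment uses
#' this: a read identified by applying transformation t must have been
#' transcribed from the template by the inverse exchange (e.g. a read
#' detected as A→T→C→G→A-transformed was transcribed
#' assuming A→G→C→T→A).
#'
#' @param t an `nt_transformation` or name.
#' @return The inverse `nt_transformation`.
#' @examples
#' invert_transformation("A-T-C-G-A")$name
#' @export
invert_transformation <- function(t) {
  t <- parse_transformation(t)
  inv <- stats::setNames(names(t$mapping), unname(t$mapping))
  if (is_identity(t)) return(identity_transformation())
  new_transformation(inv[DNA_BASES])
}

#' Compose two transformations
#'
#' Returns the bijection obtained by applying `b` first and `a` second
#' (function composition a ∘ b). The 23 transformations together with
#' the identity form the symmetric group on four letters, so the result is
#' always the identity or one of the 23.
#'
#' @param a,b `nt_transformation` objects or names (identity allowed).
#' @return An `nt_transformation` (possibly the identity).
#' @examples
#' compose_transformations("A<>T", "C<>G")$name  # the complement map
#' @export
compose_transformations <- function(a, b) {
  a <- parse_transformation(a)
  b <- parse_transformation(b)
  mapping <- stats::setNames(unname(a$mapping[unname(b$mapping)]), DNA_BASES)
  if (all(mapping == DNA_BASES)) return(identity_transformation())
  new_transformation(mapping)
}

#' The Watson-Crick complement map
#'
#' The double swap A↔T+C↔G. Conjugating a transformation by this
#' map (`c %.% t %.% c`) gives the transformation that describes the same
#' read on the opposite strand; detection uses this to canonicalize
#' reverse-strand hits.
#'
#' @return An `nt_transformation`.
#' @export
complement_transformation <- function() {
  parse_transformation(paste0("A", ARROW_SWAP, "T+C", ARROW_SWAP, "G"))
}

# conjugate of t by the complement map, used for strand canonicalization
conjugate_by_complement <- function(t) {
  cc <- complement_transformation()
  compose_transformations(cc, compose_transformations(t, cc))
}

# number of bases moved by the transformation (2, 3 or 4); used for the
# deterministic tie-break between equally scoring transformations
transformation_support <- function(t) sum(t$mapping != DNA_BASES)

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N and IUPAC codes).
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTMRWSYKVHDBNacgtmrwsykvhdbn",
                 "TGCAKYWSRMBDHVNtgcakywsrmbdhvn", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Tabulate the 23 transformations
#'
#' One row per transformation: canonical name, kind, cycle type and the
#' image of each base.
#'
#' @return A data.frame with columns `name`, `kind`, `cycle_type`,
#'   `A`, `C`, `G`, `T`.
#' @export
transformation_table <- function() {
  tr <- transformation_set()
  data.frame(
    name = vapply(tr, `[[`, character(1), "name"),
    kind = vapply(tr, `[[`, character(1), "kind"),
    cycle_type = vapply(tr, `[[`, character(1), "cycle_type"),
    A = vapply(tr, function(t) t$mapping[["A"]], character(1)),
    C = vapply(tr, function(t) t$mapping[["C"]], character(1)),
    G = vapply(tr, function(t) t$mapping[["G"]], character(1)),
    T = vapply(tr, function(t) t$mapping[["T"]], character(1)),
    row.names = NULL
  )
}

#' Write the transformation table to a tab-separated file
#'
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_transformation_table <- function(path) {
  utils::write.table(transformation_table(), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
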