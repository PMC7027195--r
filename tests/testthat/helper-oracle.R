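# shared test utilities: tiny independent oracles and random-sequence helpers

random_dna <- function(n, gc = 0.5) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# all 24 permutations of the 4 bases, built independently of the package
oracle_permutations <- function() {
  perms <- list()
  for (p in asplit(as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4)), 1)) {
    if (length(unique(p)) == 4L) {
      perms[[length(perms) + 1L]] <-
        setNames(c("A", "C", "G", "T")[p], c("A", "C", "G", "T"))
    }
  }
  perms
}

oracle_apply <- function(mapping, seq) {
  chartr("ACGT", paste(mapping[c("A", "C", "G", "T")], collapse = ""), seq)
}

# best ungapped local alignment score of query against reference over all
# diagonals (Kadane maximum-subarray per diagonal); a lower bound on the
# affine-gap Smith-Waterman score with the same match/mismatch scores
oracle_ungapped_best <- function(query, reference, match = 2, mismatch = -3) {
  q <- strsplit(query, "")[[1]]
  r <- strsplit(reference, "")[[1]]
  m <- length(q)
  n <- length(r)
  best <- 0
  for (off in (1 - m):(n - 1)) {
    i <- max(1, 1 - off):min(m, n - off)
    sc <- ifelse(q[i] == r[i + off], match, mismatch)
    run <- 0
    for (s in sc) {
      run <- max(0, run + s)
      best <- max(best, run)
    }
  }
  best
}

# exhaustive (transformation x orientation x diagonal) oracle for the best
# ungapped explanation of a read; returns the best score and the set of
# argmax transformation names (forward-strand canonical form)
oracle_detect <- function(read, refs, match = 2, mismatch = -3) {
  perms <- oracle_permutations()
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  best <- 0
  argmax <- character(0)
  for (mapping in perms) {
    for (orient in c("+", "-")) {
      x <- oracle_apply(mapping, if (orient == "+") read else rc(read))
      sc <- max(vapply(refs, function(r) oracle_ungapped_best(x, r, match, mismatch),
                       numeric(1)))
      # forward-strand canonical transformation for this description
      t_obj <- swingerseq:::new_transformation(mapping)
      if (orient == "-") t_obj <- swingerseq:::conjugate_by_complement(t_obj)
      if (sc > best) {
        best <- sc
        argmax <- t_obj$name
      } else if (sc == best && sc > 0) {
        argmax <- union(argmax, t_obj$name)
      }
    }
  }
  list(score = best, transformations = argmax)
}
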