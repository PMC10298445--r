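# Independent brute-force oracles the implementation is checked against.

# Naive per-gene, per-tissue double-loop specificity caller.
oracle_caller <- function(m, config = caller_config()) {
  out <- list()
  for (i in seq_len(nrow(m))) {
    if (max(m[i, ]) < config$detection_threshold) next
    for (j in seq_len(ncol(m))) {
      if (m[i, j] <= config$high_threshold) next
      others <- m[i, -j]
      ok <- all(others < config$low_threshold)
      if (config$off_target_strict_positive) ok <- ok && all(others > 0)
      if (ok) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = rownames(m)[i], target_tissue = colnames(m)[j],
          target_fpkm = m[i, j], max_off_target_fpkm = max(others),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(0), target_tissue = character(0),
                      target_fpkm = numeric(0), max_off_target_fpkm = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Exhaustive-enumeration hypergeometric upper tail P(X >= k).
oracle_hypergeom <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Degenerate-expansion scanner: expand the consensus into every concrete
# word, literal-search each word (both strands) with overlap, palindrome
# dedup on start. Valid for N-free subject sequences.
expand_consensus <- function(consensus) {
  sets <- lapply(strsplit(toupper(consensus), NULL)[[1]],
                 function(c) tsgenes:::IUPAC_SETS[[c]])
  words <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  apply(words[, rev(seq_along(sets)), drop = FALSE], 1, paste, collapse = "")
}

literal_starts <- function(word, seq) {
  m <- gregexpr(paste0("(?=", word, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

oracle_scan <- function(seq, library, both_strands = TRUE) {
  seq <- toupper(seq)
  out <- list()
  for (i in seq_len(nrow(library))) {
    cons <- library$consensus[i]
    w <- nchar(cons)
    fwd <- sort(unique(unlist(lapply(expand_consensus(cons),
                                     literal_starts, seq = seq))))
    rev <- integer(0)
    if (both_strands) {
      rc_words <- revcomp_iupac(expand_consensus(cons))
      rev <- sort(unique(unlist(lapply(rc_words, literal_starts, seq = seq))))
      rev <- setdiff(rev, fwd)
    }
    if (length(fwd) + length(rev) == 0) next
    out[[length(out) + 1L]] <- data.frame(
      motif = library$name[i],
      start = c(fwd, rev) - 1L,
      strand = c(rep("+", length(fwd)), rep("-", length(rev))),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(motif = character(0), start = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$motif, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Brute-force agglomerative complete-linkage merge heights (no leaf order).
oracle_complete_heights <- function(m) {
  d <- as.matrix(dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      h <- max(d[clusters[[a]], clusters[[b]]])
      if (h < best[1]) best <- c(h, a, b)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# Random valid FPKM matrix for round-trip / property tests.
random_matrix <- function(n_genes, n_tissues, seed) {
  with_seed <- get("with_seed", envir = asNamespace("tsgenes"))
  with_seed(seed, {
    m <- matrix(round(rlnorm(n_genes * n_tissues, 2, 2), 6), n_genes, n_tissues)
    dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                        sprintf("t%02d", seq_len(n_tissues)))
    m
  })
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
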