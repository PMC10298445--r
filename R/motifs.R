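#' Built-in library of tissue-specificity cis-elements
#'
#' Eleven classic PLACE-style promoter elements whose experimental
#' characterisation ties them to tissue-specific expression, from
#' root-hair (RHERPATEXPA7) through seed (RYREPEATBNNAPA) to pollen
#' (POLLEN2LELAT52). Consensus strings use the IUPAC degenerate alphabet.
#'
#' @return data.frame with columns `name`, `consensus`, `tissue_class`.
#' @export
builtin_motif_library <- function() {
  lib <- data.frame(
    name = c("RHERPATEXPA7", "SITEIIATCYTC", "NODCON1GM",
             "TGTCACACMCUCUMISIN", "AACACOREOSGLUB1", "DPBFCOREDCDC3",
             "ACGTOSGLUB1", "GCN4OSGLUB1", "RYREPEATBNNAPA",
             "POLLEN2LELAT52", "CANBNNAPA"),
    consensus = c("KCACGW", "TGGGCY", "AAAGAT",
                  "TGTCACA", "AACAAAC", "ACACNNG",
                  "GTACGTG", "TGAGTCA", "CATGCA",
                  "TCCACCATA", "CNAACAC"),
    tissue_class = c("root-hair-specific", "anther- and meristem-specific",
                     "nodule-specific", "fruit-specific",
                     "endosperm-specific", "embryo-specific",
                     "endosperm-specific", "endosperm-specific",
                     "seed-specific", "pollen-specific",
                     "embryo- and endosperm-specific"),
    stringsAsFactors = FALSE)
  class(lib) <- c("motif_library", "data.frame")
  lib
}

check_motif_library <- function(lib) {
  stopifnot(is.data.frame(lib),
            all(c("name", "consensus", "tissue_class") %in% colnames(lib)))
  dup <- unique(lib$name[duplicated(lib$name)])
  if (length(dup)) stop_validation("duplicate motif name(s): ", paste(dup, collapse = ", "))
  for (i in seq_len(nrow(lib))) {
    cons <- lib$consensus[i]
    if (!nzchar(cons)) stop_validation("motif '", lib$name[i], "': empty consensus")
    ch <- strsplit(toupper(cons), NULL)[[1L]]
    bad <- which(!ch %in% IUPAC_CODES)
    if (length(bad)) {
      stop_validation("motif '", lib$name[i], "': invalid IUPAC character '",
                      ch[bad[1L]], "' at position ", bad[1L])
    }
  }
  invisible(lib)
}

#' Load a motif library table
#'
#' Three-column TSV (`name`, `consensus`, `tissue_class`), validated
#' against the IUPAC alphabet. Use this to extend or replace
#' [builtin_motif_library()].
#'
#' @param path TSV path, no header.
#' @return validated `motif_library` data.frame.
#' @export
load_motif_table <- function(path) {
  if (!file.exists(path)) stop_validation("motif table not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop_validation("motif table needs columns name, consensus, tissue_class")
  lib <- data.frame(name = raw[[1L]], consensus = toupper(raw[[2L]]),
                    tissue_class = raw[[3L]], stringsAsFactors = FALSE)
  check_motif_library(lib)
  class(lib) <- c("motif_library", "data.frame")
  lib
}

#' Write a motif library table
#'
#' @param lib a `motif_library` data.frame.
#' @param path output TSV path.
#' @export
write_motif_table <- function(lib, path) {
  check_motif_library(lib)
  utils::write.table(lib[, c("name", "consensus", "tissue_class")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(NULL)
}

#' Match a degenerate IUPAC consensus against a concrete window
#'
#' TRUE iff at every position the window base belongs to the IUPAC set of
#' the consensus symbol. A window base `N` (unknown sequence) matches only
#' a consensus `N`: unknown bases are treated conservatively so that runs
#' of N can never fabricate a specific element match.
#'
#' @param consensus IUPAC string.
#' @param window concrete A/C/G/T/N string of the same length.
#' @return logical scalar.
#' @export
iupac_match <- function(consensus, window) {
  if (nchar(consensus) != nchar(window)) {
    stop_validation("consensus and window lengths differ (",
                    nchar(consensus), " vs ", nchar(window), ")")
  }
  cc <- strsplit(toupper(consensus), NULL)[[1L]]
  wc <- strsplit(toupper(window), NULL)[[1L]]
  for (i in seq_along(cc)) {
    if (wc[i] == "N") {
      if (cc[i] != "N") return(FALSE)
    } else if (!wc[i] %in% IUPAC_SETS[[cc[i]]]) {
      return(FALSE)
    }
  }
  TRUE
}

# Regex character class implementing iupac_match semantics for one symbol:
# consensus N also admits sequence N, any other symbol only concrete bases.
iupac_regex <- function(consensus) {
  ch <- strsplit(toupper(consensus), NULL)[[1L]]
  paste(vapply(ch, function(c) {
    set <- IUPAC_SETS[[c]]
    if (c == "N") "[ACGTN]" else paste0("[", paste(set, collapse = ""), "]")
  }, ""), collapse = "")
}

# 1-based start positions of all (overlapping) regex matches.
regex_starts <- function(regex, seq) {
  m <- gregexpr(paste0("(?=", regex, ")"), seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Scan a promoter for cis-element occurrences
#'
#' Every overlapping window position is tested against each motif's
#' consensus on the given strand and, unless `both_strands = FALSE`,
#' against its reverse complement (reported as strand `-` at the same
#' coordinates). When a palindromic consensus matches a window both ways,
#' the hit is reported once (strand `+`). Overlapping occurrences all
#' count, following the element-database convention of reporting motif
#' occurrences rather than coverage.
#'
#' @param promoter a promoter sequence (character scalar) or a one-row
#'   data.frame from [extract_promoters()].
#' @param library a `motif_library` data.frame.
#' @param promoter_id id used in the output when `promoter` is a bare
#'   string.
#' @param both_strands scan the reverse complement of each consensus too.
#' @return data.frame sorted by (start, motif, strand): `promoter_id`,
#'   `motif`, `start`, `end` (0-based half-open offsets in the promoter),
#'   `strand`, `matched` (the concrete matched substring).
#' @export
scan_promoter <- function(promoter, library = builtin_motif_library(),
                          promoter_id = "promoter", both_strands = TRUE) {
  if (is.data.frame(promoter)) {
    stopifnot(nrow(promoter) == 1L)
    promoter_id <- promoter$gene_id
    promoter <- promoter$sequence
  }
  check_motif_library(library)
  seq <- toupper(promoter)
  hits <- list()
  for (i in seq_len(nrow(library))) {
    cons <- toupper(library$consensus[i])
    w <- nchar(cons)
    if (nchar(seq) < w) next
    fwd <- regex_starts(iupac_regex(cons), seq)
    rev <- if (both_strands) regex_starts(iupac_regex(revcomp_iupac(cons)), seq)
           else integer(0)
    rev <- setdiff(rev, fwd)  # palindrome: count the shared window once, as +
    n_f <- length(fwd); n_r <- length(rev)
    if (n_f + n_r == 0L) next
    starts <- c(fwd, rev)
    hits[[length(hits) + 1L]] <- data.frame(
      promoter_id = promoter_id,
      motif = library$name[i],
      start = starts - 1L, end = starts - 1L + w,
      strand = c(rep("+", n_f), rep("-", n_r)),
      matched = substring(seq, starts, starts + w - 1L),
      stringsAsFactors = FALSE)
  }
  if (!length(hits)) {
    return(data.frame(promoter_id = character(0), motif = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), matched = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$motif, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a set of promoters
#'
#' @param records data.frame from [extract_promoters()] (columns `gene_id`,
#'   `sequence`), or a named character vector of sequences.
#' @inheritParams scan_promoter
#' @return combined hit data.frame across promoters (see [scan_promoter()]).
#' @export
scan_promoters <- function(records, library = builtin_motif_library(),
                           both_strands = TRUE) {
  if (is.character(records)) {
    records <- data.frame(gene_id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  out <- lapply(seq_len(nrow(records)), function(i)
    scan_promoter(records[i, , drop = FALSE], library, both_strands = both_strands))
  res <- do.call(rbind, out)
  if (is.null(res)) res <- scan_promoter("", library)
  rownames(res) <- NULL
  res
}

#' Cis-element distribution across promoters
#'
#' Summarises scanner hits into the promoter x motif count matrix behind
#' element-distribution figures, plus per-promoter proportions of each
#' tissue class among all elements found in that promoter.
#'
#' @param hits data.frame from [scan_promoters()].
#' @param library the `motif_library` the hits came from.
#' @param promoter_ids optional ids fixing row order (and including
#'   promoters with zero hits).
#' @return list with `counts` (promoter x motif integer matrix),
#'   `class_proportions` (promoter x tissue-class matrix, rows of zero-hit
#'   promoters reported as 0), `class_overall` (named vector, each class's
#'   share of all hits), and `no_hits` (logical per promoter).
#' @export
distribution_table <- function(hits, library = builtin_motif_library(),
                               promoter_ids = NULL) {
  check_motif_library(library)
  if (is.null(promoter_ids)) promoter_ids <- unique(hits$promoter_id)
  counts_tab <- table(factor(hits$promoter_id, levels = promoter_ids),
                      factor(hits$motif, levels = library$name))
  counts <- matrix(as.integer(counts_tab), nrow = length(promoter_ids),
                   dimnames = list(promoter_ids, library$name))
  classes <- unique(library$tissue_class)
  class_counts <- vapply(classes, function(cl) {
    rowSums(counts[, library$tissue_class == cl, drop = FALSE])
  }, numeric(length(promoter_ids)))
  class_counts <- matrix(class_counts, nrow = length(promoter_ids),
                         dimnames = list(promoter_ids, classes))
  totals <- rowSums(counts)
  props <- class_counts / ifelse(totals > 0, totals, 1)
  overall <- if (sum(totals) > 0) colSums(class_counts) / sum(totals)
             else stats::setNames(rep(0, length(classes)), classes)
  list(counts = counts, class_proportions = props,
       class_overall = overall, no_hits = stats::setNames(totals == 0, promoter_ids))
}
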