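#' Read a genome FASTA into a chromosome map
#'
#' @param path FASTA path.
#' @return named character vector, chromosome id -> uppercase sequence.
#'   Ids are truncated at the first whitespace, as aligners do.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop_validation("genome FASTA not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop_validation("duplicate sequence id(s) in FASTA: ", paste(dup, collapse = ", "))
  }
  stats::setNames(toupper(as.character(ss)), ids)
}

#' Gene models (translation start positions) from GFF3
#'
#' Parses gene/mRNA/CDS features linked by `ID`/`Parent` attributes and
#' reduces each gene to the genomic position of the first base of its
#' start codon on the representative transcript: the minimum CDS start on
#' the plus strand, the maximum CDS end on the minus strand.
#'
#' The representative transcript is the mRNA whose ID carries the `.1`
#' suffix; failing that, the one with the longest total CDS; remaining
#' ties break lexicographically. Genes without any CDS are skipped with a
#' warning.
#'
#' @param path GFF3 path.
#' @return data.frame with columns `gene_id`, `chrom`, `strand` (`+`/`-`),
#'   `cds_start` (1-based genomic position of the start codon's first base).
#' @export
read_annotation_gff3 <- function(path) {
  if (!file.exists(path)) stop_validation("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$Parent1 <- vapply(df$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, "")
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]

  out <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$ID[i]
    tx <- mrnas[!is.na(mrnas$Parent1) & mrnas$Parent1 == gid, , drop = FALSE]
    tx_cds <- lapply(tx$ID, function(tid)
      cds[!is.na(cds$Parent1) & cds$Parent1 == tid, , drop = FALSE])
    has_cds <- vapply(tx_cds, nrow, 0L) > 0L
    tx <- tx[has_cds, , drop = FALSE]
    tx_cds <- tx_cds[has_cds]
    if (nrow(tx) == 0L) {
      warning("gene '", gid, "' has no CDS; skipped")
      return(NULL)
    }
    rep_i <- which(endsWith(tx$ID, ".1"))
    if (length(rep_i) != 1L) {
      cds_len <- vapply(tx_cds, function(d) sum(d$end - d$start + 1L), 0L)
      rep_i <- which(cds_len == max(cds_len))
      if (length(rep_i) > 1L) rep_i <- rep_i[order(tx$ID[rep_i])][1L]
    }
    d <- tx_cds[[rep_i]]
    strand <- as.character(tx$strand[rep_i])
    if (!strand %in% c("+", "-")) {
      stop_validation("gene '", gid, "': strand must be + or -")
    }
    data.frame(gene_id = gid,
               chrom = as.character(tx$seqnames[rep_i]),
               strand = strand,
               cds_start = if (strand == "+") min(d$start) else max(d$end),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), cds_start = integer(0),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Extract promoter sequences upstream of the translation start
#'
#' The promoter of a gene is the `length` bases immediately 5' of the
#' first base of its start codon, strand-aware and excluding the ATG
#' itself. On the plus strand this is genomic
#' `[cds_start - 1 - length, cds_start - 1)` (0-based half-open); on the
#' minus strand it is `[cds_start, cds_start + length)`
#' reverse-complemented, so the returned sequence always reads 5' to 3'
#' relative to the gene. Windows running off a chromosome end are clipped
#' (never padded) and flagged `truncated`.
#'
#' @param genome named character vector from [read_genome()].
#' @param models data.frame from [read_annotation_gff3()].
#' @param length promoter length in bases; default 3000 (3 kb).
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open genomic interval), `strand`, `length`, `truncated`,
#'   `sequence`.
#' @export
extract_promoters <- function(genome, models, length = 3000) {
  stopifnot(length >= 1, is.character(genome), !is.null(names(genome)))
  length <- as.integer(length)
  rows <- lapply(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    if (!m$chrom %in% names(genome)) {
      stop_validation("gene '", m$gene_id, "': chromosome '", m$chrom,
                      "' not in genome")
    }
    chrom_len <- nchar(genome[[m$chrom]])
    if (m$cds_start < 1L || m$cds_start > chrom_len) {
      stop_validation("gene '", m$gene_id, "': CDS start ", m$cds_start,
                      " outside chromosome '", m$chrom, "' (length ", chrom_len, ")")
    }
    if (m$strand == "+") {
      end0 <- as.integer(m$cds_start) - 1L
      start0 <- max(0L, end0 - length)
    } else {
      start0 <- as.integer(m$cds_start)
      end0 <- min(chrom_len, start0 + length)
    }
    got <- end0 - start0
    seq <- if (got > 0L) substr(genome[[m$chrom]], start0 + 1L, end0) else ""
    if (m$strand == "-") seq <- revcomp_iupac(seq)
    if (got == 0L) {
      warning("gene '", m$gene_id, "' has a zero-length promoter (gene at chromosome edge)")
    }
    data.frame(gene_id = m$gene_id, chrom = m$chrom,
               start = start0, end = end0, strand = m$strand,
               length = got, truncated = got < length, sequence = seq,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0), strand = character(0),
                      length = integer(0), truncated = logical(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Write promoters as FASTA plus BED6
#'
#' The FASTA holds the strand-oriented promoter sequences (id = gene id);
#' the BED6 holds the genomic intervals (0-based half-open) with the
#' strand column, names suffixed `_truncated` for clipped records.
#'
#' @param records data.frame from [extract_promoters()].
#' @param fasta_path,bed_path output paths.
#' @export
write_promoters <- function(records, fasta_path, bed_path) {
  ss <- Biostrings::DNAStringSet(records$sequence)
  names(ss) <- records$gene_id
  tryCatch(Biostrings::writeXStringSet(ss, fasta_path),
           error = function(e) stop_validation("cannot write FASTA to ",
                                               fasta_path, ": ", conditionMessage(e)))
  bed <- data.frame(
    chrom = records$chrom, start = records$start, end = records$end,
    name = paste0(records$gene_id, ifelse(records$truncated, "_truncated", "")),
    score = 0L, strand = records$strand, stringsAsFactors = FALSE)
  tryCatch(utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                              row.names = FALSE, col.names = FALSE),
           error = function(e) stop_validation("cannot write BED to ",
                                               bed_path, ": ", conditionMessage(e)))
  invisible(NULL)
}
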