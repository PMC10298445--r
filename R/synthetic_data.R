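#' Simulate an FPKM atlas with planted tissue-specific genes
#'
#' Emulates the structure of a bulk soybean expression atlas: a large gene
#' catalog over nine tissues in which a small planted fraction is
#' tissue-specific, a fraction is undetected everywhere, and the remaining
#' background genes carry skewed (log-normal-bodied) profiles constructed
#' to violate the specificity rule. Defaults reproduce the atlas-scale
#' study conditions: 56,044 genes, nine tissues, 288 specific genes
#' distributed 117 flower / 99 seed / 40 root / 21 leaf / 3 stem /
#' 2 nodule, and 3,731 undetected genes.
#'
#' Planted specific genes draw their target FPKM log-uniformly on
#' \[150, 20000\] -- populating all four expression bins including the
#' >5000 tail seen for seed genes -- and off-target FPKM uniformly on
#' \[0, 8\]; undetected genes draw all tissues uniformly on \[0, 0.5\].
#' These margins keep every planted gene at least 1.25x clear of the
#' default caller thresholds, so planted truth is exactly recoverable.
#' Background genes take one of three profiles, all detected and none
#' callable: `broad` (two tissues above the high threshold), `leaky` (one
#' high tissue plus an off-target in \[10, 90\]) or `moderate` (all
#' tissues in \[1.5, 90\]).
#'
#' @param n_genes catalog size.
#' @param tissues tissue labels (>= 2).
#' @param spec_per_tissue named integer vector, tissue -> number of planted
#'   specific genes.
#' @param n_undetected number of planted undetected genes.
#' @param seed RNG seed; the generator is a pure function of it.
#' @return list with `matrix` (gene x tissue FPKM) and `truth` (list:
#'   `specific` data.frame `gene_id`/`tissue`/`target_fpkm`, `undetected`
#'   ids, `background` ids).
#' @export
gen_expression_matrix <- function(
    n_genes = 56044,
    tissues = c("leaf", "stem", "sam", "flower", "pod", "seed", "root",
                "root_hair", "nodule"),
    spec_per_tissue = c(flower = 117, seed = 99, root = 40, leaf = 21,
                        stem = 3, nodule = 2),
    n_undetected = 3731,
    seed = 1) {
  stopifnot(length(tissues) >= 2L, !anyDuplicated(tissues))
  if (!all(names(spec_per_tissue) %in% tissues)) {
    stop_validation("spec_per_tissue names must be tissue labels")
  }
  n_spec <- sum(spec_per_tissue)
  if (n_spec + n_undetected > n_genes) {
    stop_validation("planted specific + undetected genes exceed n_genes")
  }
  nt <- length(tissues)
  with_seed(seed, {
    gene_ids <- sprintf("Gene%06d", seq_len(n_genes))
    perm <- sample.int(n_genes)
    spec_idx <- perm[seq_len(n_spec)]
    undet_idx <- perm[n_spec + seq_len(n_undetected)]
    bg_idx <- perm[-seq_len(n_spec + n_undetected)]
    m <- matrix(0, n_genes, nt, dimnames = list(gene_ids, tissues))

    spec_tissue <- rep(names(spec_per_tissue), spec_per_tissue)
    if (n_spec > 0L) {
      m[spec_idx, ] <- matrix(runif(n_spec * nt, 0, 8), n_spec, nt)
      target_fpkm <- exp(runif(n_spec, log(150), log(20000)))
      m[cbind(spec_idx, match(spec_tissue, tissues))] <- target_fpkm
    } else {
      target_fpkm <- numeric(0)
    }
    if (n_undetected > 0L) {
      m[undet_idx, ] <- matrix(runif(n_undetected * nt, 0, 0.5),
                               n_undetected, nt)
    }
    n_bg <- length(bg_idx)
    if (n_bg > 0L) {
      base <- matrix(pmin(rlnorm(n_bg * nt, meanlog = 1, sdlog = 1.5), 90),
                     n_bg, nt)
      mode <- sample(c("broad", "leaky", "moderate"), n_bg, replace = TRUE)
      col1 <- sample.int(nt, n_bg, replace = TRUE)
      col2 <- 1L + (col1 - 1L + sample.int(nt - 1L, n_bg, replace = TRUE)) %% nt
      is_b <- mode == "broad"; is_l <- mode == "leaky"; is_m <- mode == "moderate"
      base[cbind(which(is_b), col1[is_b])] <- runif(sum(is_b), 150, 5000)
      base[cbind(which(is_b), col2[is_b])] <- runif(sum(is_b), 150, 5000)
      base[cbind(which(is_l), col1[is_l])] <- runif(sum(is_l), 150, 5000)
      base[cbind(which(is_l), col2[is_l])] <- runif(sum(is_l), 10, 90)
      base[is_m, ] <- matrix(runif(sum(is_m) * nt, 1.5, 90), sum(is_m), nt)
      m[bg_idx, ] <- base
    }
    truth <- list(
      specific = data.frame(gene_id = gene_ids[spec_idx], tissue = spec_tissue,
                            target_fpkm = target_fpkm, stringsAsFactors = FALSE),
      undetected = gene_ids[undet_idx],
      background = gene_ids[bg_idx])
    list(matrix = m, truth = truth)
  })
}

#' Simulate a toy genome with annotated, ATG-initiated genes
#'
#' Writes a single random chromosome (FASTA) and a GFF3 annotation of
#' `n_genes` two-exon protein-coding genes on alternating strands, each
#' with an ATG-initiated CDS, plus the ground-truth translation-start
#' table. When `edge_genes = TRUE` the first gene is placed 500 bp from
#' the chromosome start (and, when strands allow, the last gene 400 bp
#' from the end) so that default-length promoter extraction truncates.
#'
#' @param n_genes number of genes.
#' @param chrom_length chromosome length in bp.
#' @param seed RNG seed.
#' @param dir output directory for `genome.fa` and `genes.gff3`.
#' @param cds_length total CDS length per gene (multiple of 3).
#' @param edge_genes place boundary genes close to the chromosome ends.
#' @return list with `fasta`, `gff` (paths) and `models` (truth
#'   data.frame `gene_id`, `chrom`, `strand`, `cds_start`).
#' @export
gen_genome_annotation <- function(n_genes = 10, chrom_length = 100000,
                                  seed = 1, dir = tempdir(),
                                  cds_length = 300, edge_genes = TRUE) {
  stopifnot(cds_length %% 3 == 0, cds_length >= 9)
  chrom_length <- as.integer(chrom_length)
  cds_length <- as.integer(cds_length)
  spacing <- chrom_length %/% n_genes
  intron_len <- 80L
  footprint <- cds_length + intron_len
  if (spacing < footprint + 600L) {
    stop_validation("chromosome too short for ", n_genes,
                    " genes (need >= ", n_genes * (footprint + 600L), " bp)")
  }
  with_seed(seed, {
    chrom <- paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
                   collapse = "")
    models <- vector("list", n_genes)
    gff <- c("##gff-version 3")
    for (i in seq_len(n_genes)) {
      gid <- sprintf("gene%03d", i)
      strand <- if (i %% 2L == 1L) "+" else "-"
      slot <- (i - 1L) * spacing
      lo <- slot + 500L
      hi <- slot + spacing - footprint
      if (!edge_genes) {
        # keep a full default promoter inside the chromosome on both ends
        if (strand == "+") lo <- max(lo, 3001L)
        else hi <- min(hi, chrom_length - 3000L - footprint + 1L)
        if (hi < lo) stop_validation("chromosome too short for untruncated promoters")
      }
      a <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      if (edge_genes && i == 1L) a <- 501L
      if (edge_genes && i == n_genes && strand == "-") {
        a <- chrom_length - 400L - footprint + 1L
      }
      l1 <- 3L * sample(1:(cds_length %/% 3L - 1L), 1L)
      l2 <- cds_length - l1
      cds_seq <- paste0("ATG",
                        paste(sample(c("A", "C", "G", "T"),
                                     cds_length - 6L, replace = TRUE),
                              collapse = ""), "TAA")
      e <- a + footprint - 1L
      if (strand == "+") {
        ex1 <- c(a, a + l1 - 1L)
        ex2 <- c(a + l1 + intron_len, e)
        substr(chrom, ex1[1L], ex1[2L]) <- substr(cds_seq, 1L, l1)
        substr(chrom, ex2[1L], ex2[2L]) <- substr(cds_seq, l1 + 1L, cds_length)
        cds_start <- a
      } else {
        # minus strand: first CDS segment is the highest-coordinate exon
        ex_hi <- c(e - l1 + 1L, e)
        ex_lo <- c(a, a + l2 - 1L)
        substr(chrom, ex_hi[1L], ex_hi[2L]) <- revcomp_iupac(substr(cds_seq, 1L, l1))
        substr(chrom, ex_lo[1L], ex_lo[2L]) <- revcomp_iupac(substr(cds_seq, l1 + 1L, cds_length))
        ex1 <- ex_lo; ex2 <- ex_hi
        cds_start <- e
      }
      phase2 <- (3L - l1 %% 3L) %% 3L
      gff <- c(gff,
        paste("chr1", "tsg", "gene", a, e, ".", strand, ".",
              paste0("ID=", gid), sep = "\t"),
        paste("chr1", "tsg", "mRNA", a, e, ".", strand, ".",
              paste0("ID=", gid, ".1;Parent=", gid), sep = "\t"),
        paste("chr1", "tsg", "CDS", ex1[1L], ex1[2L], ".", strand,
              if (strand == "+") "0" else as.character(phase2),
              paste0("ID=cds_", gid, ";Parent=", gid, ".1"), sep = "\t"),
        paste("chr1", "tsg", "CDS", ex2[1L], ex2[2L], ".", strand,
              if (strand == "+") as.character(phase2) else "0",
              paste0("ID=cds_", gid, ";Parent=", gid, ".1"), sep = "\t"))
      models[[i]] <- data.frame(gene_id = gid, chrom = "chr1", strand = strand,
                                cds_start = as.integer(cds_start),
                                stringsAsFactors = FALSE)
    }
    fasta_path <- file.path(dir, "genome.fa")
    gff_path <- file.path(dir, "genes.gff3")
    writeLines(c(">chr1", substring(chrom, seq(1, chrom_length, 70),
                                    pmin(seq(1, chrom_length, 70) + 69, chrom_length))),
               fasta_path)
    writeLines(gff, gff_path)
    list(fasta = fasta_path, gff = gff_path, models = do.call(rbind, models))
  })
}

#' Plant cis-element words into synthetic promoter sequences
#'
#' Generates i.i.d. background sequence at a stated GC content, then
#' overwrites it with concrete realisations of the requested motifs at
#' the requested positions (reverse-complemented for minus-strand
#' placements). Degenerate consensus positions are resolved to a concrete
#' base, recorded in the truth table so scanner output can be checked
#' exactly. Background sequence can of course contain chance matches;
#' planted hits are guaranteed, chance hits are the scanner's business.
#'
#' @param n_promoters number of promoter sequences.
#' @param length length of each promoter in bases.
#' @param placements data.frame with columns `promoter` (index or id),
#'   `motif` (name in `library`), `start` (0-based offset), `strand`
#'   (`+`/`-`). Placements within a promoter must not overlap.
#' @param library motif library supplying the consensus strings.
#' @param background_gc background GC content in \[0, 1\].
#' @param seed RNG seed.
#' @return list with `sequences` (named character vector, ids `prom01`...)
#'   and `truth` (data.frame `promoter_id`, `motif`, `start`, `strand`,
#'   `word` -- the concrete planted word as it appears on the plus strand
#'   of the promoter for `+`, before reverse complementing for `-`).
#' @export
plant_motifs <- function(n_promoters, length = 3000, placements = NULL,
                         library = builtin_motif_library(),
                         background_gc = 0.4, seed = 1) {
  check_motif_library(library)
  stopifnot(background_gc >= 0, background_gc <= 1)
  ids <- sprintf("prom%02d", seq_len(n_promoters))
  with_seed(seed, {
    p_base <- c(A = (1 - background_gc) / 2, C = background_gc / 2,
                G = background_gc / 2, T = (1 - background_gc) / 2)
    seqs <- vapply(seq_len(n_promoters), function(i) {
      paste(sample(names(p_base), length, replace = TRUE, prob = p_base),
            collapse = "")
    }, "")
    names(seqs) <- ids
    truth <- data.frame(promoter_id = character(0), motif = character(0),
                        start = integer(0), strand = character(0),
                        word = character(0), stringsAsFactors = FALSE)
    if (!is.null(placements) && nrow(placements)) {
      pid <- placements$promoter
      if (is.numeric(pid)) pid <- ids[pid]
      rows <- vector("list", nrow(placements))
      for (j in seq_len(nrow(placements))) {
        cons <- library$consensus[match(placements$motif[j], library$name)]
        if (is.na(cons)) {
          stop_validation("unknown motif '", placements$motif[j], "'")
        }
        w <- nchar(cons)
        start0 <- placements$start[j]
        if (start0 < 0L || start0 + w > length) {
          stop_validation("placement ", j, " outside promoter")
        }
        word <- paste(vapply(strsplit(toupper(cons), NULL)[[1L]], function(c) {
          sample(IUPAC_SETS[[c]], 1L)
        }, ""), collapse = "")
        planted <- if (placements$strand[j] == "+") word else revcomp_iupac(word)
        substr(seqs[[pid[j]]], start0 + 1L, start0 + w) <- planted
        rows[[j]] <- data.frame(promoter_id = pid[j],
                                motif = placements$motif[j],
                                start = start0, strand = placements$strand[j],
                                word = word, stringsAsFactors = FALSE)
      }
      truth <- do.call(rbind, rows)
      # overlap check per promoter
      for (p in unique(truth$promoter_id)) {
        d <- truth[truth$promoter_id == p, , drop = FALSE]
        w <- nchar(library$consensus[match(d$motif, library$name)])
        ord <- order(d$start)
        s <- d$start[ord]; e <- d$start[ord] + w[ord]
        if (any(s[-1L] < e[-length(e)])) {
          stop_validation("overlapping placements in promoter '", p, "'")
        }
      }
    }
    list(sequences = seqs, truth = truth)
  })
}

#' Simulate a qPCR Ct table with planted fold-changes
#'
#' Per tissue and replicate, a reference (housekeeping) Ct is drawn as
#' `base_ct + Normal(0, noise_sd)`; each target gene's Ct in that
#' replicate is the reference Ct minus log2 of its planted fold-change
#' plus independent noise, so its expected 2^-dCt relative expression
#' equals the fold. A planted fold of 0 yields a non-detected (`ND`)
#' reaction.
#'
#' @param fold_map data.frame with columns `gene_id`, `tissue`, `fold`
#'   (>= 0), one row per gene-tissue pair to simulate.
#' @param noise_sd Ct noise standard deviation, in cycles.
#' @param n_replicates replicates per gene-tissue pair (>= 2).
#' @param seed RNG seed.
#' @param reference_gene housekeeping gene id.
#' @param base_ct mean reference Ct, in cycles.
#' @return a `ct_table` (see [load_ct_table()]).
#' @export
gen_ct_table <- function(fold_map, noise_sd = 0.2, n_replicates = 3,
                         seed = 1, reference_gene = "GmActin", base_ct = 20) {
  stopifnot(noise_sd >= 0, n_replicates >= 2,
            all(c("gene_id", "tissue", "fold") %in% colnames(fold_map)),
            all(fold_map$fold >= 0))
  tissues <- unique(fold_map$tissue)
  reps <- sprintf("r%d", seq_len(n_replicates))
  with_seed(seed, {
    ref <- expand.grid(tissue = tissues, replicate = reps,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ref$gene_id <- reference_gene
    ref$ct <- base_ct + rnorm(nrow(ref), 0, noise_sd)
    ref$detected <- TRUE

    idx <- rep(seq_len(nrow(fold_map)), each = n_replicates)
    tgt <- data.frame(gene_id = fold_map$gene_id[idx],
                      tissue = fold_map$tissue[idx],
                      replicate = rep(reps, times = nrow(fold_map)),
                      stringsAsFactors = FALSE)
    key_ref <- paste(ref$tissue, ref$replicate)
    ref_ct <- ref$ct[match(paste(tgt$tissue, tgt$replicate), key_ref)]
    fold <- fold_map$fold[idx]
    tgt$ct <- ifelse(fold > 0,
                     ref_ct - log2(pmax(fold, .Machine$double.xmin)) +
                       rnorm(nrow(tgt), 0, noise_sd),
                     NA_real_)
    tgt$detected <- fold > 0
    cols <- c("gene_id", "tissue", "replicate", "ct", "detected")
    ct_table(rbind(tgt[, cols], ref[, cols]), reference_gene)
  })
}

#' Fold-change design for a qPCR validation experiment
#'
#' Builds the inputs for a seeded validation simulation: `n_true` genes
#' whose planted fold-change excess sits in their predicted tissue, and
#' `n_false` genes whose excess is planted in a different tissue (so a
#' correct analysis must reject them). All other tissues get fold 1.
#'
#' @param n_true genes planted consistently with their prediction.
#' @param n_false genes planted in a non-predicted tissue.
#' @param fold planted fold-change of the high tissue over the rest.
#' @param tissues tissue panel.
#' @return list with `fold_map` (data.frame for [gen_ct_table()]) and
#'   `predictions` (named vector gene -> predicted tissue).
#' @export
validation_design <- function(n_true = 10, n_false = 2, fold = 64,
                              tissues = c("leaf", "stem", "root", "flower",
                                          "seed", "pod")) {
  stopifnot(length(tissues) >= 2L)
  n <- n_true + n_false
  genes <- sprintf("val%02d", seq_len(n))
  predicted <- tissues[(seq_len(n) - 1L) %% length(tissues) + 1L]
  high <- predicted
  if (n_false > 0L) {
    mis <- n_true + seq_len(n_false)
    high[mis] <- tissues[(match(predicted[mis], tissues)) %% length(tissues) + 1L]
  }
  fold_map <- expand.grid(gene_id = genes, tissue = tissues,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fold_map$fold <- ifelse(fold_map$tissue == high[match(fold_map$gene_id, genes)],
                          fold, 1)
  list(fold_map = fold_map, predictions = stats::setNames(predicted, genes))
}
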