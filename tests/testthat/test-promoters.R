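# Minimal in-code GFF3 fixture: rows of (type, start, end, strand, ID, Parent)
write_gff <- function(rows) {
  lines <- c("##gff-version 3", vapply(rows, function(r) {
    attrs <- paste0("ID=", r[[5]], if (!is.na(r[[6]])) paste0(";Parent=", r[[6]]))
    paste("chr1", "test", r[[1]], r[[2]], r[[3]], ".", r[[4]], ".", attrs,
          sep = "\t")
  }, ""))
  p <- tempfile(fileext = ".gff3")
  writeLines(lines, p)
  p
}

write_fasta <- function(seqs) {
  p <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))), p)
  p
}

test_that("FASTA genomes load case-normalised with unique ids", {
  p <- write_fasta(c(chrA = "acgtACGT"))
  g <- read_genome(p)
  expect_identical(g, c(chrA = "ACGTACGT"))
  dup <- write_fasta(c(chrA = "ACGT", chrA = "GGGG"))
  expect_error(read_genome(dup), "duplicate sequence id")
})

test_that("translation start comes from the representative transcript, strand-aware", {
  p <- write_gff(list(
    list("gene", 3001, 3900, "+", "gplus", NA),
    list("mRNA", 3001, 3900, "+", "gplus.1", "gplus"),
    list("CDS", 3001, 3900, "+", "cds1", "gplus.1"),
    list("gene", 100, 900, "-", "gminus", NA),
    list("mRNA", 100, 900, "-", "gminus.1", "gminus"),
    list("CDS", 100, 900, "-", "cds2", "gminus.1")))
  models <- read_annotation_gff3(p)
  expect_identical(models$cds_start[models$gene_id == "gplus"], 3001L)
  expect_identical(models$cds_start[models$gene_id == "gminus"], 900L)
})

test_that("isoform choice: .1 suffix, then longest CDS, then lexicographic", {
  p <- write_gff(list(
    list("gene", 1000, 2000, "+", "gA", NA),
    list("mRNA", 1000, 2000, "+", "gA.1", "gA"),
    list("CDS", 1200, 1400, "+", "cA1", "gA.1"),
    list("mRNA", 1000, 2000, "+", "gA.2", "gA"),
    list("CDS", 1100, 1900, "+", "cA2", "gA.2"),     # longer, but .1 wins
    list("gene", 5000, 6000, "+", "gB", NA),
    list("mRNA", 5000, 6000, "+", "gB.2", "gB"),
    list("CDS", 5100, 5200, "+", "cB2", "gB.2"),
    list("mRNA", 5000, 6000, "+", "gB.3", "gB"),
    list("CDS", 5300, 5900, "+", "cB3", "gB.3")))    # longest CDS wins
  models <- read_annotation_gff3(p)
  expect_identical(models$cds_start[models$gene_id == "gA"], 1200L)
  expect_identical(models$cds_start[models$gene_id == "gB"], 5300L)
})

test_that("genes without CDS are skipped with a warning", {
  p <- write_gff(list(
    list("gene", 100, 200, "+", "gX", NA),
    list("mRNA", 100, 200, "+", "gX.1", "gX")))
  expect_warning(models <- read_annotation_gff3(p), "no CDS")
  expect_identical(nrow(models), 0L)
})

test_that("promoter intervals anchor just upstream of the start codon", {
  with_seed <- get("with_seed", envir = asNamespace("tsgenes"))
  chrom <- with_seed(4, paste(sample(c("A", "C", "G", "T"), 6000, TRUE),
                              collapse = ""))
  genome <- c(chr1 = chrom)
  models <- data.frame(gene_id = c("gfull", "gclip"), chrom = "chr1",
                       strand = "+", cds_start = c(3001L, 500L),
                       stringsAsFactors = FALSE)
  pr <- extract_promoters(genome, models, length = 3000)
  full <- pr[pr$gene_id == "gfull", ]
  expect_identical(c(full$start, full$end), c(0L, 3000L))
  expect_false(full$truncated)
  expect_identical(full$sequence, substr(chrom, 1, 3000))
  clip <- pr[pr$gene_id == "gclip", ]
  expect_identical(clip$length, 499L)
  expect_true(clip$truncated)
  expect_identical(nchar(pr$sequence), pr$end - pr$start)
})

test_that("minus-strand promoters are the reverse complement downstream slice", {
  genome <- c(chr1 = "AAACATGGGGGTTTTT")
  # start codon at genomic 6..4 on the minus strand (revcomp of CAT at 4..6)
  models <- data.frame(gene_id = "gm", chrom = "chr1", strand = "-",
                       cds_start = 6L, stringsAsFactors = FALSE)
  pr <- extract_promoters(genome, models, length = 5)
  expect_identical(c(pr$start, pr$end), c(6L, 11L))
  expect_identical(pr$sequence, revcomp_iupac(substr(genome, 7, 11)))
})

test_that("strand-mirror invariance: extraction commutes with genome reversal", {
  ga <- gen_genome_annotation(n_genes = 6, chrom_length = 60000, seed = 13,
                              dir = tempdir(), edge_genes = FALSE)
  genome <- read_genome(ga$fasta)
  models <- ga$models
  pr <- extract_promoters(genome, models)
  L <- nchar(genome[["chr1"]])
  mirror_genome <- c(chr1 = revcomp_iupac(genome[["chr1"]]))
  mirror_models <- models
  mirror_models$strand <- ifelse(models$strand == "+", "-", "+")
  mirror_models$cds_start <- L - models$cds_start + 1L
  pr2 <- extract_promoters(mirror_genome, mirror_models)
  expect_identical(pr2$sequence, pr$sequence)
  expect_identical(pr2$truncated, pr$truncated)
})

test_that("generator genes translate from ATG and round-trip through the reader", {
  ga <- gen_genome_annotation(n_genes = 8, chrom_length = 80000, seed = 21,
                              dir = tempdir())
  genome <- read_genome(ga$fasta)
  models <- read_annotation_gff3(ga$gff)
  expect_identical(models[order(models$gene_id), ],
                   ga$models[order(ga$models$gene_id), ])
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    codon <- if (m$strand == "+") {
      substr(genome[[m$chrom]], m$cds_start, m$cds_start + 2)
    } else {
      revcomp_iupac(substr(genome[[m$chrom]], m$cds_start - 2, m$cds_start))
    }
    expect_identical(codon, "ATG")
  }
  # promoter never overlaps the start codon
  pr <- extract_promoters(genome, models)
  expect_true(all(pr$length <= 3000))
  expect_identical(sum(pr$truncated), 2L)  # both edge genes clip
})

test_that("out-of-bounds coordinates and unknown chromosomes are hard errors", {
  genome <- c(chr1 = "ACGTACGT")
  bad_pos <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                        cds_start = 99L, stringsAsFactors = FALSE)
  expect_error(extract_promoters(genome, bad_pos), "outside chromosome")
  bad_chr <- data.frame(gene_id = "g", chrom = "chrZ", strand = "+",
                        cds_start = 2L, stringsAsFactors = FALSE)
  expect_error(extract_promoters(genome, bad_chr), "not in genome")
  edge <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                     cds_start = 1L, stringsAsFactors = FALSE)
  expect_warning(pr <- extract_promoters(genome, edge), "zero-length")
  expect_identical(pr$length, 0L)
  expect_true(pr$truncated)
})

test_that("written FASTA and BED are self-consistent with the genome", {
  ga <- gen_genome_annotation(n_genes = 4, chrom_length = 40000, seed = 30,
                              dir = tempdir())
  genome <- read_genome(ga$fasta)
  pr <- extract_promoters(genome, ga$models)
  fa <- tempfile(fileext = ".fa"); bed <- tempfile(fileext = ".bed")
  write_promoters(pr, fa, bed)
  back <- read_genome(fa)
  expect_identical(unname(back), pr$sequence)
  bed_df <- read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  expect_identical(bed_df$V3 - bed_df$V2, pr$length)
  expect_true(all(grepl("_truncated$", bed_df$V4[pr$truncated])))
  for (i in seq_len(nrow(bed_df))) {
    sl <- substr(genome[[bed_df$V1[i]]], bed_df$V2[i] + 1, bed_df$V3[i])
    if (bed_df$V6[i] == "-") sl <- revcomp_iupac(sl)
    expect_identical(sl, pr$sequence[i])
  }
})
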