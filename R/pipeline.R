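#' Pipeline configuration
#'
#' Bundles every tunable of the discovery workflow. The defaults are the
#' canonical settings of the atlas-mining strategy: specificity thresholds
#' 100 / 10 FPKM with a 1-FPKM detection floor, 3-kb promoters, and a
#' p < 0.05 enrichment rule.
#'
#' @param thresholds a [caller_config()].
#' @param promoter_length promoter window in bases.
#' @param alpha enrichment significance level.
#' @param motif_library `"builtin"` or a path for [load_motif_table()].
#' @param out_dir directory for stage outputs.
#' @param seed seed recorded in the run summary (the analysis itself is
#'   deterministic).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(thresholds = caller_config(),
                            promoter_length = 3000, alpha = 0.05,
                            motif_library = "builtin",
                            out_dir = "tsg_output", seed = NULL) {
  stopifnot(inherits(thresholds, "caller_config"),
            promoter_length >= 1, alpha > 0, alpha < 1)
  structure(list(thresholds = thresholds, promoter_length = promoter_length,
                 alpha = alpha, motif_library = motif_library,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Run the full discovery pipeline
#'
#' Orchestrates: detection filter, specificity calling, expression
#' binning, row Z-scores with complete-linkage leaf order, optional term
#' enrichment of the called genes, and -- when genome and annotation are
#' supplied -- promoter extraction of called genes, cis-element scanning,
#' and the element distribution table. Every stage output is written under
#' `config$out_dir` as plain text plus a machine-readable `summary.json`.
#' Reruns with the same inputs and configuration are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param matrix_path expression matrix TSV (see
#'   [read_expression_matrix()]).
#' @param genome_path,gff_path optional genome FASTA and GFF3; both or
#'   neither.
#' @param annotation_path optional gene-to-term TSV for [enrich()].
#' @param delimiter expression matrix field separator.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config, matrix_path, genome_path = NULL,
                         gff_path = NULL, annotation_path = NULL,
                         delimiter = "\t") {
  stopifnot(inherits(config, "pipeline_config"))
  if (xor(is.null(genome_path), is.null(gff_path))) {
    stop_validation("supply both genome_path and gff_path, or neither")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  m <- read_expression_matrix(matrix_path, delimiter = delimiter)
  flt <- filter_undetected(m, config$thresholds)
  writeLines(flt$undetected_gene_ids, out("undetected_genes.txt"))

  calls <- call_tissue_specific(flt$detected, config$thresholds)
  utils::write.table(calls, out("specific_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bins <- bin_by_level(calls, tissues = colnames(m))
  utils::write.table(data.frame(tissue = rownames(bins), bins,
                                check.names = FALSE),
                     out("bin_counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  summary <- list(
    n_genes = nrow(m),
    tissues = colnames(m),
    n_undetected = length(flt$undetected_gene_ids),
    pct_undetected = 100 * length(flt$undetected_gene_ids) / nrow(m),
    n_detected = nrow(flt$detected),
    n_specific = nrow(calls),
    calls_per_tissue = as.list(stats::setNames(
      as.integer(rowSums(bins)), rownames(bins))),
    bin_totals = as.list(stats::setNames(as.integer(colSums(bins)),
                                         colnames(bins))),
    seed = config$seed)

  if (nrow(calls) > 0L) {
    z <- row_zscore(m[calls$gene_id, , drop = FALSE])
    ord <- cluster_order(z)
    utils::write.table(data.frame(gene_id = rownames(z), z, check.names = FALSE),
                       out("zscores.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(rownames(z)[ord], out("heatmap_leaf_order.txt"))
  }

  if (!is.null(annotation_path)) {
    ann <- load_annotation(annotation_path)
    res <- enrich(intersect(calls$gene_id, ann$background), ann,
                  alpha = config$alpha)
    utils::write.table(res, out("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$n_terms_tested <- nrow(res)
    summary$n_terms_significant <- sum(res$significant)
  }

  if (!is.null(genome_path)) {
    genome <- read_genome(genome_path)
    models <- read_annotation_gff3(gff_path)
    models <- models[models$gene_id %in% calls$gene_id, , drop = FALSE]
    proms <- extract_promoters(genome, models, length = config$promoter_length)
    write_promoters(proms, out("promoters.fa"), out("promoters.bed"))
    lib <- if (identical(config$motif_library, "builtin")) builtin_motif_library()
           else load_motif_table(config$motif_library)
    hits <- scan_promoters(proms, lib)
    utils::write.table(hits, out("motif_hits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    dist <- distribution_table(hits, lib, promoter_ids = proms$gene_id)
    utils::write.table(data.frame(promoter_id = rownames(dist$counts),
                                  dist$counts, check.names = FALSE),
                       out("element_distribution.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$n_promoters <- nrow(proms)
    summary$n_truncated_promoters <- sum(proms$truncated)
    summary$n_motif_hits <- nrow(hits)
  }

  stopifnot(sum(unlist(summary$calls_per_tissue)) == summary$n_specific)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}
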