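#' Thresholds for the tissue-specificity caller
#'
#' A gene is called specific for a tissue when its FPKM there exceeds
#' `high_threshold` while every other tissue stays below `low_threshold`.
#' Genes whose maximum FPKM across all tissues falls below
#' `detection_threshold` are treated as undetected and removed before
#' calling. Defaults (100 / 10 / 1 FPKM) are the conventional settings for
#' atlas-scale specificity screens.
#'
#' `off_target_strict_positive = TRUE` additionally requires every
#' off-target FPKM to be strictly positive (the literal "0 < FPKM < 10"
#' reading); the default admits fully silent off-target tissues, since a
#' gene that is high in one tissue and absent everywhere else is the
#' clearest possible specific gene.
#'
#' @param high_threshold FPKM the target tissue must exceed (strict `>`).
#' @param low_threshold FPKM every other tissue must stay under (strict `<`).
#' @param detection_threshold genes with max FPKM below this (strict `<`)
#'   in all tissues count as undetected.
#' @param off_target_strict_positive require off-target FPKM > 0.
#' @return an object of class `caller_config`.
#' @export
caller_config <- function(high_threshold = 100, low_threshold = 10,
                          detection_threshold = 1,
                          off_target_strict_positive = FALSE) {
  stopifnot(is.numeric(high_threshold), is.numeric(low_threshold),
            is.numeric(detection_threshold))
  if (!(0 <= detection_threshold && detection_threshold <= low_threshold &&
        low_threshold < high_threshold)) {
    stop_validation("need 0 <= detection_threshold <= low_threshold < high_threshold")
  }
  structure(list(high_threshold = high_threshold,
                 low_threshold = low_threshold,
                 detection_threshold = detection_threshold,
                 off_target_strict_positive = isTRUE(off_target_strict_positive)),
            class = "caller_config")
}

#' @export
print.caller_config <- function(x, ...) {
  cat("Tissue-specificity caller configuration\n",
      "  target tissue:     FPKM > ", x$high_threshold, "\n",
      "  other tissues:     FPKM ", if (x$off_target_strict_positive) "in (0, "
      else "< ", x$low_threshold, if (x$off_target_strict_positive) ")", "\n",
      "  detection floor:   max FPKM >= ", x$detection_threshold, "\n", sep = "")
  invisible(x)
}

#' Split a matrix into detected and undetected genes
#'
#' A gene is undetected when its maximum FPKM across all tissues is below
#' the detection threshold (strict `<`; a gene reaching the threshold
#' exactly in one tissue counts as detected). The two parts partition the
#' input and preserve its row order.
#'
#' @param matrix gene x tissue FPKM matrix.
#' @param config a [caller_config()].
#' @return list with `detected` (sub-matrix) and `undetected_gene_ids`.
#' @export
filter_undetected <- function(matrix, config = caller_config()) {
  viol <- validate_matrix(matrix)
  if (length(viol)) stop_validation("invalid matrix: ", viol[1L])
  undet <- apply(matrix, 1L, max) < config$detection_threshold
  list(detected = matrix[!undet, , drop = FALSE],
       undetected_gene_ids = rownames(matrix)[undet])
}

#' Call tissue-specific genes by FPKM thresholds
#'
#' A gene is assigned to tissue `t` when FPKM(t) strictly exceeds the high
#' threshold and every other tissue is below the low threshold. The
#' thresholds guarantee at most one call per gene. Undetected genes are
#' filtered out first.
#'
#' @param matrix gene x tissue FPKM matrix.
#' @param config a [caller_config()].
#' @return data.frame with columns `gene_id`, `target_tissue`,
#'   `target_fpkm`, `max_off_target_fpkm`, `bin`, sorted by target tissue
#'   (matrix column order) and then by descending target FPKM.
#' @export
call_tissue_specific <- function(matrix, config = caller_config()) {
  det <- filter_undetected(matrix, config)$detected
  empty <- data.frame(gene_id = character(0), target_tissue = character(0),
                      target_fpkm = numeric(0), max_off_target_fpkm = numeric(0),
                      bin = character(0), stringsAsFactors = FALSE)
  if (nrow(det) == 0L) return(empty)

  hi <- det > config$high_threshold
  cand <- rowSums(hi) == 1L
  if (!any(cand)) return(empty)
  sub <- det[cand, , drop = FALSE]
  tcol <- max.col(hi[cand, , drop = FALSE], ties.method = "first")
  masked <- sub
  masked[cbind(seq_len(nrow(sub)), tcol)] <- -Inf
  max_off <- apply(masked, 1L, max)
  ok <- max_off < config$low_threshold
  if (config$off_target_strict_positive) {
    masked2 <- sub
    masked2[cbind(seq_len(nrow(sub)), tcol)] <- Inf
    ok <- ok & apply(masked2, 1L, min) > 0
  }
  if (!any(ok)) return(empty)

  calls <- data.frame(
    gene_id = rownames(sub)[ok],
    target_tissue = colnames(det)[tcol[ok]],
    target_fpkm = sub[cbind(which(ok), tcol[ok])],
    max_off_target_fpkm = pmax(max_off[ok], 0),
    stringsAsFactors = FALSE)
  # bins are defined from 100 FPKM up; calls made under a lowered high
  # threshold fall outside the binning convention and get NA
  calls$bin <- NA_character_
  binnable <- calls$target_fpkm > FPKM_BIN_BREAKS[1L]
  calls$bin[binnable] <- bin_fpkm(calls$target_fpkm[binnable])
  ord <- order(match(calls$target_tissue, colnames(det)), -calls$target_fpkm)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Assign target FPKM values to expression-level bins
#'
#' Bins are half-open: \[100, 500), \[500, 1000), \[1000, 5000),
#' \[5000, Inf) -- a boundary value belongs to the upper bin, so the four
#' bins tile the whole range above 100 with no gaps.
#'
#' @param x numeric FPKM values, each > 100.
#' @return character vector of bin labels.
#' @export
bin_fpkm <- function(x) {
  if (any(x <= FPKM_BIN_BREAKS[1L])) {
    stop_validation("bin undefined for FPKM <= ", FPKM_BIN_BREAKS[1L],
                    " (a specific call requires target FPKM above the high threshold)")
  }
  as.character(cut(x, breaks = FPKM_BIN_BREAKS, labels = FPKM_BIN_LABELS,
                   right = FALSE))
}

#' Count tissue-specific calls per (tissue, expression bin)
#'
#' @param calls data.frame from [call_tissue_specific()].
#' @param tissues optional tissue labels fixing row order (and including
#'   tissues with zero calls); defaults to the tissues present in `calls`.
#' @return integer matrix, tissues x bins; row sums equal per-tissue call
#'   counts.
#' @export
bin_by_level <- function(calls, tissues = NULL) {
  if (nrow(calls) && any(calls$target_fpkm <= FPKM_BIN_BREAKS[1L])) {
    stop_validation("call with target FPKM <= ", FPKM_BIN_BREAKS[1L])
  }
  if (is.null(tissues)) tissues <- unique(calls$target_tissue)
  tab <- table(factor(calls$target_tissue, levels = tissues),
               factor(bin_fpkm(calls$target_fpkm), levels = FPKM_BIN_LABELS))
  m <- matrix(as.integer(tab), nrow = length(tissues),
              dimnames = list(tissues, FPKM_BIN_LABELS))
  m
}

#' Summarise an expression bin as a share of all calls
#'
#' Turns a per-tissue count matrix from [bin_by_level()] into the kind of
#' figure quoted in atlas reports, e.g. "21 of 288 specific genes (7.29%)
#' were expressed at 1000-5000 FPKM".
#'
#' @param bin_counts integer matrix from [bin_by_level()], or a named
#'   numeric vector of per-tissue counts for a single bin.
#' @param total total number of calls the percentage is taken over;
#'   defaults to the grand total of `bin_counts`.
#' @return data.frame with columns `bin`, `count`, `percent` (0-100 scale).
#' @export
bin_report <- function(bin_counts, total = sum(bin_counts)) {
  if (total <= 0) stop_validation("total must be positive")
  if (is.matrix(bin_counts)) {
    counts <- colSums(bin_counts)
  } else {
    counts <- c(total_bin = sum(bin_counts))
  }
  data.frame(bin = names(counts), count = as.numeric(counts),
             percent = 100 * as.numeric(counts) / total,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Row Z-score transformation for heatmaps
#'
#' Each row is centred and scaled to (x - mean) / sd with the sample
#' standard deviation (n - 1 denominator), the convention used by R's
#' heatmap tooling. Constant rows have no scale and are mapped to all-zero,
#' with a warning naming them.
#'
#' @param matrix gene x tissue matrix, >= 2 columns.
#' @return matrix of the same shape with standardised rows.
#' @export
row_zscore <- function(matrix) {
  if (ncol(matrix) < 2L) stop_validation("row Z-scores need >= 2 tissues")
  mu <- rowMeans(matrix)
  centred <- matrix - mu
  s <- sqrt(rowSums(centred^2) / (ncol(matrix) - 1L))
  const <- s == 0
  if (any(const)) {
    warning("constant row(s) mapped to all-zero Z-scores: ",
            paste(utils::head(rownames(matrix)[const], 5L), collapse = ", "),
            if (sum(const) > 5L) ", ...")
    s[const] <- 1
  }
  centred / s
}

#' Complete-linkage leaf order for heatmap rows
#'
#' Agglomerative hierarchical clustering of rows with Euclidean distance
#' and complete linkage (the distance between clusters is their maximum
#' pairwise member distance), returning the dendrogram leaf order as
#' 1-based row indices. This is the ordering a row-clustered heatmap of the
#' Z-scored matrix displays.
#'
#' @param zmatrix numeric matrix, typically from [row_zscore()].
#' @return integer vector of row indices in leaf order.
#' @export
cluster_order <- function(zmatrix) {
  n <- nrow(zmatrix)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  stats::hclust(stats::dist(zmatrix, method = "euclidean"),
                method = "complete")$order
}
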