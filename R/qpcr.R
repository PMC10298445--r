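#' Load a qPCR Ct table
#'
#' CSV with columns `gene_id`, `tissue`, `replicate`, `ct`. A `ct` cell of
#' `ND`, `N.D.` or empty marks a non-detected reaction. Rows of the
#' reference (housekeeping) gene are identified by `reference_gene`; every
#' (gene, tissue) with target measurements must have reference
#' measurements in the same tissue, since relative expression is computed
#' within-sample.
#'
#' @param path CSV path with header.
#' @param reference_gene id of the housekeeping gene (e.g. `"GmActin"`).
#' @return object of class `ct_table`: list with `data` (data.frame
#'   `gene_id`, `tissue`, `replicate`, `ct`, `detected`) and
#'   `reference_gene`.
#' @export
load_ct_table <- function(path, reference_gene = "GmActin") {
  if (!file.exists(path)) stop_validation("Ct table not found: ", path)
  raw <- utils::read.delim(path, sep = ",", header = TRUE,
                           colClasses = "character", stringsAsFactors = FALSE)
  need <- c("gene_id", "tissue", "replicate", "ct")
  if (!all(need %in% colnames(raw))) {
    stop_validation("Ct table needs columns: ", paste(need, collapse = ", "))
  }
  ct_raw <- trimws(raw$ct)
  nd <- ct_raw %in% c("", "ND", "N.D.", "nd", "NA")
  ct <- suppressWarnings(as.numeric(ct_raw))
  bad <- which(!nd & (is.na(ct) | ct <= 0))
  if (length(bad)) {
    stop_validation("invalid Ct value '", ct_raw[bad[1L]], "' at row ", bad[1L],
                    " (gene '", raw$gene_id[bad[1L]], "')")
  }
  ct[nd] <- NA_real_
  tab <- ct_table(data.frame(gene_id = raw$gene_id, tissue = raw$tissue,
                             replicate = raw$replicate, ct = ct,
                             detected = !nd, stringsAsFactors = FALSE),
                  reference_gene)
  tab
}

# Construct and validate a ct_table from an in-memory data.frame.
ct_table <- function(data, reference_gene) {
  target <- data[data$gene_id != reference_gene & data$detected, , drop = FALSE]
  ref_tissues <- unique(data$tissue[data$gene_id == reference_gene & data$detected])
  missing <- setdiff(unique(target$tissue), ref_tissues)
  if (length(missing)) {
    stop_validation("reference gene '", reference_gene,
                    "' not measured in tissue(s): ", paste(missing, collapse = ", "))
  }
  structure(list(data = data, reference_gene = reference_gene),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  tg <- setdiff(unique(x$data$gene_id), x$reference_gene)
  cat("qPCR Ct table:", length(tg), "target gene(s) x",
      length(unique(x$data$tissue)), "tissue(s), reference =",
      x$reference_gene, "\n")
  invisible(x)
}

#' Write a Ct table back to CSV
#'
#' Inverse of [load_ct_table()]; non-detected reactions are written as
#' `ND`.
#'
#' @param table a `ct_table`.
#' @param path output CSV path.
#' @export
write_ct_table <- function(table, path) {
  d <- table$data
  out <- data.frame(gene_id = d$gene_id, tissue = d$tissue,
                    replicate = d$replicate,
                    ct = ifelse(d$detected, formatC(d$ct, digits = 17, format = "g"), "ND"),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Relative expression by the 2^-dCt method
#'
#' For each replicate r (pairing target and reference by replicate id
#' within the tissue), relative expression is
#' `2^-(Ct_gene,r - Ct_ref,r)`; its log2 is minus the delta-Ct. Replicates
#' without a detected reference partner are dropped with a warning.
#'
#' @param table a `ct_table`.
#' @param gene target gene id.
#' @param tissue tissue label.
#' @return numeric vector of per-replicate relative expression values;
#'   length 0 when the gene is not detected in the tissue.
#' @export
relative_expression <- function(table, gene, tissue) {
  d <- table$data
  g <- d[d$gene_id == gene & d$tissue == tissue & d$detected, , drop = FALSE]
  if (nrow(g) == 0L) return(numeric(0))
  r <- d[d$gene_id == table$reference_gene & d$tissue == tissue & d$detected, ,
         drop = FALSE]
  common <- intersect(g$replicate, r$replicate)
  if (length(common) < nrow(g)) {
    warning("gene '", gene, "' in '", tissue, "': dropping ",
            nrow(g) - length(common), " replicate(s) without a reference pair")
  }
  if (length(common) == 0L) return(numeric(0))
  gct <- g$ct[match(common, g$replicate)]
  rct <- r$ct[match(common, r$replicate)]
  2^-(gct - rct)
}

#' Compare relative expression between two tissues
#'
#' Two-sided two-sample Student's t-test on log2-transformed relative
#' expression (log2 stabilises the multiplicative qPCR scale). The classic
#' equal-variance test is the default; set `var_equal = FALSE` for Welch.
#' Degenerate inputs where both groups are constant are resolved without a
#' test: p = 1 for equal means, p = 0 otherwise.
#'
#' @param values_target,values_other per-replicate relative expression
#'   (linear scale, > 0), at least 2 replicates each.
#' @param alpha unused in the p computation, kept for interface symmetry.
#' @param var_equal pool variances (Student) or not (Welch).
#' @return list with `p_value` and `code` (`***` p < 0.001, `**` p < 0.01,
#'   else `n.s.`).
#' @export
compare_tissues <- function(values_target, values_other, alpha = 0.05,
                            var_equal = TRUE) {
  if (length(values_target) < 2L || length(values_other) < 2L) {
    stop_validation("need >= 2 replicates per group for a t-test")
  }
  x <- log2(values_target); y <- log2(values_other)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    p <- if (mean(x) == mean(y)) 1 else 0
  } else {
    p <- stats::t.test(x, y, var.equal = var_equal)$p.value
  }
  code <- if (p < 0.001) "***" else if (p < 0.01) "**" else "n.s."
  list(p_value = p, code = code)
}

#' Validate predicted tissue specificity against qPCR data
#'
#' A prediction is confirmed (`specific`) when the predicted tissue has
#' the strictly highest mean relative expression among detected tissues
#' AND the target differs significantly (p < `alpha`, pairwise Student's
#' t-test on log2 values) from every other detected tissue. Tissues where
#' the gene is entirely non-detected cannot defeat specificity -- they
#' contribute no comparison. A gene not detected in its predicted tissue
#' is `not_detected`.
#'
#' @param table a `ct_table`.
#' @param predictions named character vector, gene id -> predicted tissue,
#'   or a data.frame with columns `gene_id`, `tissue`.
#' @param alpha significance level for the pairwise tests.
#' @param var_equal see [compare_tissues()].
#' @return object of class `qpcr_validation`: list with `verdicts`
#'   (data.frame `gene_id`, `predicted_tissue`, `target_mean`,
#'   `max_other_mean`, `verdict`), `comparisons` (data.frame `gene_id`,
#'   `tissue`, `p_value`, `code`), and `consistency` (percentage, 0-100,
#'   of predictions confirmed).
#' @export
validate_specificity <- function(table, predictions, alpha = 0.05,
                                 var_equal = TRUE) {
  if (is.data.frame(predictions)) {
    predictions <- stats::setNames(predictions$tissue, predictions$gene_id)
  }
  genes <- names(predictions)
  absent <- setdiff(genes, unique(table$data$gene_id))
  if (length(absent)) {
    stop_validation("predicted gene(s) missing from Ct table: ",
                    paste(absent, collapse = ", "))
  }
  tissues <- unique(table$data$tissue)
  verdicts <- vector("list", length(genes))
  comparisons <- list()
  for (i in seq_along(genes)) {
    gene <- genes[i]; target <- unname(predictions[i])
    re <- lapply(tissues, function(tt) relative_expression(table, gene, tt))
    names(re) <- tissues
    detected <- names(re)[lengths(re) > 0L]
    if (!target %in% detected) {
      verdicts[[i]] <- data.frame(gene_id = gene, predicted_tissue = target,
                                  target_mean = NA_real_, max_other_mean = NA_real_,
                                  verdict = "not_detected", stringsAsFactors = FALSE)
      next
    }
    means <- vapply(re[detected], mean, 0)
    others <- setdiff(detected, target)
    highest <- all(means[target] > means[others])
    all_sig <- TRUE
    for (tt in others) {
      cmp <- compare_tissues(re[[target]], re[[tt]], alpha, var_equal)
      comparisons[[length(comparisons) + 1L]] <- data.frame(
        gene_id = gene, tissue = tt, p_value = cmp$p_value, code = cmp$code,
        stringsAsFactors = FALSE)
      if (cmp$p_value >= alpha) all_sig <- FALSE
    }
    verdicts[[i]] <- data.frame(
      gene_id = gene, predicted_tissue = target,
      target_mean = unname(means[target]),
      max_other_mean = if (length(others)) max(means[others]) else NA_real_,
      verdict = if (highest && all_sig) "specific" else "not_specific",
      stringsAsFactors = FALSE)
  }
  verdicts <- do.call(rbind, verdicts)
  rownames(verdicts) <- NULL
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons)
    else data.frame(gene_id = character(0), tissue = character(0),
                    p_value = numeric(0), code = character(0))
  structure(list(verdicts = verdicts, comparisons = comparisons,
                 consistency = 100 * sum(verdicts$verdict == "specific") /
                   nrow(verdicts)),
            class = "qpcr_validation")
}

#' @export
print.qpcr_validation <- function(x, ...) {
  cat("qPCR specificity validation:", nrow(x$verdicts), "prediction(s),",
      sum(x$verdicts$verdict == "specific"), "confirmed (",
      sprintf("%.2f%%", x$consistency), "consistency )\n")
  print(x$verdicts)
  invisible(x)
}
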