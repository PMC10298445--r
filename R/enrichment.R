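#' Load a gene-to-term annotation map
#'
#' Reads a two- or three-column table (`gene_id`, `term_id`, optional
#' `description`) into the structure used by [enrich()]. Duplicate
#' (gene, term) lines collapse to one membership (set semantics). The
#' background universe defaults to every gene appearing in the file; pass
#' `background` to widen it (e.g. to the full expression matrix's genes).
#'
#' @param path TSV path, no header.
#' @param background optional character vector of background gene ids; must
#'   contain every annotated gene.
#' @return object of class `annotation_map`: list with `terms` (named list
#'   term -> character vector of genes), `descriptions`, `background`.
#' @export
load_annotation <- function(path, background = NULL) {
  if (!file.exists(path)) stop_validation("annotation file not found: ", path)
  if (length(readLines(path, n = 1L)) == 0L) {
    stop_validation("annotation file is empty: ", path)
  }
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop_validation("annotation needs columns gene_id, term_id")
  genes <- raw[[1L]]
  terms <- raw[[2L]]
  term_genes <- lapply(split(genes, terms), unique)
  desc <- NULL
  if (ncol(raw) >= 3L) {
    desc <- vapply(split(raw[[3L]], terms), function(d) d[1L], "")
  }
  bg <- if (is.null(background)) unique(genes) else unique(background)
  missing_bg <- setdiff(genes, bg)
  if (length(missing_bg)) {
    stop_validation("annotated gene(s) missing from background: ",
                    paste(utils::head(missing_bg, 5L), collapse = ", "))
  }
  structure(list(terms = term_genes, descriptions = desc, background = bg),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("Annotation map:", length(x$terms), "terms over",
      length(x$background), "background genes\n")
  invisible(x)
}

#' One-sided hypergeometric over-representation p-value
#'
#' Upper-tail probability P(X >= k) for X ~ Hypergeometric(N, K, n): the
#' chance that a random draw of `n` genes from a background of `N`, of
#' which `K` carry the term, contains at least the `k` term genes observed
#' in the study set. This is the classic over-representation test behind
#' GO/KEGG enrichment tools.
#'
#' @param k study genes carrying the term.
#' @param n study set size.
#' @param K background genes carrying the term.
#' @param N background size.
#' @return p-value in \[0, 1\].
#' @export
hypergeom_pvalue <- function(k, n, K, N) {
  stopifnot(length(k) == 1L, length(n) == 1L, length(K) == 1L, length(N) == 1L)
  if (!(k >= 0 && n >= 0 && K >= 0 && N >= 0 &&
        k <= min(n, K) && n <= N && K <= N)) {
    stop_validation("need 0 <= k <= min(n, K), n <= N, K <= N; got k=", k,
                    " n=", n, " K=", K, " N=", N)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term over-representation in a study gene set
#'
#' Tests every annotation term with at least one study gene for
#' over-representation with [hypergeom_pvalue()]. Significance follows the
#' raw p-value rule `p < alpha` by default; Benjamini-Hochberg adjusted
#' p-values are reported alongside and can drive the flag instead via
#' `flag_on = "adjusted"`.
#'
#' @param study character vector of study gene ids; genes outside the
#'   background are dropped with a warning.
#' @param annotation an [load_annotation()] result.
#' @param alpha significance level (default 0.05).
#' @param flag_on `"raw"` (default) or `"adjusted"`: which p-value the
#'   `significant` flag uses.
#' @return data.frame, one row per term with k >= 1, sorted by ascending
#'   p-value: `term_id`, `description`, `k`, `n`, `K`, `N`, `p_value`,
#'   `p_adjusted`, `significant`.
#' @export
enrich <- function(study, annotation, alpha = 0.05, flag_on = c("raw", "adjusted")) {
  flag_on <- match.arg(flag_on)
  stopifnot(inherits(annotation, "annotation_map"))
  study <- unique(study)
  outside <- setdiff(study, annotation$background)
  if (length(outside)) {
    warning("dropping ", length(outside), " study gene(s) outside the background")
    study <- setdiff(study, outside)
  }
  if (length(study) == 0L) stop_validation("study set empty after background intersection")
  n <- length(study)
  N <- length(annotation$background)
  k <- vapply(annotation$terms, function(g) length(intersect(study, g)), 0L)
  K <- lengths(annotation$terms)
  keep <- k >= 1L
  if (!any(keep)) {
    return(data.frame(term_id = character(0), description = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p_value = numeric(0),
                      p_adjusted = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  }
  res <- data.frame(
    term_id = names(annotation$terms)[keep],
    description = if (is.null(annotation$descriptions)) NA_character_
                  else unname(annotation$descriptions[names(annotation$terms)[keep]]),
    k = unname(k[keep]), n = n, K = unname(K[keep]), N = N,
    stringsAsFactors = FALSE)
  if (nrow(res) == 0L) {
    res$p_value <- numeric(0); res$p_adjusted <- numeric(0)
    res$significant <- logical(0)
    return(res)
  }
  res$p_value <- mapply(hypergeom_pvalue, res$k, res$n, res$K, res$N)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- (if (flag_on == "raw") res$p_value else res$p_adjusted) < alpha
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
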