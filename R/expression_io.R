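#' Read a gene x tissue FPKM expression matrix
#'
#' Parses a delimited text file whose first row is the tissue header and
#' whose first column holds gene identifiers, into a validated numeric
#' matrix (genes in rows, tissues in columns). Values must be non-negative,
#' finite FPKM; scientific notation is accepted and values are kept at full
#' double precision.
#'
#' If several input columns measure the same tissue (replicate libraries),
#' supply `group_map`, a named character vector mapping column name ->
#' tissue label; columns sharing a tissue label are collapsed by arithmetic
#' mean after parsing.
#'
#' @param path path to the expression table.
#' @param delimiter field separator; tab by default, use `","` for CSV.
#' @param group_map optional named character vector `c(column = tissue, ...)`
#'   used to collapse replicate columns by mean.
#' @return numeric matrix of FPKM with gene ids as rownames and tissue
#'   labels as colnames.
#' @seealso [write_expression_matrix()], [validate_matrix()]
#' @export
read_expression_matrix <- function(path, delimiter = "\t", group_map = NULL) {
  if (!file.exists(path)) stop_validation("expression matrix file not found: ", path)
  raw <- utils::read.delim(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) {
    stop_validation("expression matrix needs >= 2 tissue columns, found ",
                    ncol(raw) - 1L)
  }
  gene_ids <- raw[[1L]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) {
    stop_validation("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  }
  tissues <- colnames(raw)[-1L]
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(tissues),
                 dimnames = list(gene_ids, tissues))
  for (j in seq_along(tissues)) {
    col <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(col) | !is.finite(col) | col < 0)
    if (length(bad)) {
      i <- bad[1L]
      stop_validation("invalid FPKM value '", raw[[j + 1L]][i],
                      "' at gene '", gene_ids[i], "' (row ", i,
                      "), tissue '", tissues[j], "' (column ", j, ")")
    }
    vals[, j] <- col
  }
  if (!is.null(group_map)) {
    unmapped <- setdiff(tissues, names(group_map))
    if (length(unmapped)) {
      stop_validation("group_map is missing column(s): ",
                      paste(unmapped, collapse = ", "))
    }
    groups <- unname(group_map[tissues])
    out <- vapply(unique(groups), function(g) {
      rowMeans(vals[, groups == g, drop = FALSE])
    }, numeric(nrow(vals)))
    vals <- matrix(out, nrow = nrow(vals),
                   dimnames = list(gene_ids, unique(groups)))
    if (ncol(vals) < 2L) stop_validation("fewer than 2 tissues after grouping")
  }
  stopifnot(length(validate_matrix(vals)) == 0L)
  vals
}

#' Write an expression matrix to a delimited text file
#'
#' The output is re-readable by [read_expression_matrix()] to an identical
#' matrix: cells are serialised with 17 significant digits so doubles
#' round-trip exactly.
#'
#' @param matrix numeric gene x tissue matrix with dimnames.
#' @param path output path.
#' @param delimiter field separator (default tab).
#' @export
write_expression_matrix <- function(matrix, path, delimiter = "\t") {
  viol <- validate_matrix(matrix)
  if (length(viol)) stop_validation("invalid matrix: ", viol[1L])
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_validation("cannot write to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(matrix)), collapse = delimiter), con)
  cells <- formatC(matrix, digits = 17, format = "g")
  body <- apply(cbind(rownames(matrix), cells), 1L, paste, collapse = delimiter)
  writeLines(body, con)
  invisible(NULL)
}

#' Validate an expression matrix
#'
#' Checks the container invariants -- unique gene and tissue labels, at
#' least two tissues, all cells present, non-negative and finite -- and
#' reports violations instead of throwing, so it can be used to audit
#' questionable inputs.
#'
#' @param matrix candidate gene x tissue matrix.
#' @return character vector of human-readable violations; empty when the
#'   matrix is valid.
#' @export
validate_matrix <- function(matrix) {
  v <- character(0)
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    return("not a numeric matrix")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    v <- c(v, "missing gene or tissue labels")
  } else {
    dg <- unique(rownames(matrix)[duplicated(rownames(matrix))])
    if (length(dg)) v <- c(v, paste0("duplicate gene id: ", dg))
    dt <- unique(colnames(matrix)[duplicated(colnames(matrix))])
    if (length(dt)) v <- c(v, paste0("duplicate tissue label: ", dt))
  }
  if (ncol(matrix) < 2L) v <- c(v, "fewer than 2 tissues")
  bad <- which(is.na(matrix) | !is.finite(matrix) | matrix < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    v <- c(v, apply(bad, 1L, function(ij) {
      paste0("invalid value at gene '",
             if (!is.null(rownames(matrix))) rownames(matrix)[ij[1L]] else ij[1L],
             "', tissue '",
             if (!is.null(colnames(matrix))) colnames(matrix)[ij[2L]] else ij[2L],
             "'")
    }))
  }
  v
}
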