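#' Fold-change matrices
#'
#' Expression evidence enters the analysis as a genes-by-conditions matrix
#' of log2 fold-change values, one column per paired test/control
#' comparison. Missing values are allowed; a gene missing in a condition is
#' simply excluded from every set statistic for that condition.
#'
#' `as_fc_matrix` validates and normalizes a numeric matrix (upper-casing
#' gene symbols and checking uniqueness); `read_fc_matrix` /
#' `write_fc_matrix` handle the TSV layout (header row of condition IDs,
#' first column gene or probe symbol).
#'
#' @param x A numeric matrix with gene symbols as row names and condition
#'   identifiers as column names.
#' @param allow_duplicates Keep duplicated row identifiers (probe-level
#'   input that still needs [collapse_probes()]).
#' @return A validated numeric matrix.
#' @export
as_fc_matrix <- function(x, allow_duplicates = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("fold-change matrix needs gene row names and condition column names")
  }
  rownames(x) <- toupper(rownames(x))
  if (anyDuplicated(colnames(x))) stop("condition identifiers must be unique")
  if (!allow_duplicates && anyDuplicated(rownames(x))) {
    stop("gene symbols must be unique; collapse probe-level data first")
  }
  x
}

#' @rdname as_fc_matrix
#' @param path Path to a TSV file.
#' @export
read_fc_matrix <- function(path, allow_duplicates = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("fold-change TSV needs an id column and >= 1 condition")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  as_fc_matrix(m, allow_duplicates = allow_duplicates)
}

#' @rdname as_fc_matrix
#' @export
write_fc_matrix <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level values to gene level
#'
#' Microarray platforms measure several probes per gene; probe values that
#' correspond to the same gene are averaged (arithmetic mean per condition,
#' ignoring missing values). Probes absent from the map are dropped; a
#' probe mapped to more than one gene is an error.
#'
#' @param x Probe-level matrix (probes x conditions), duplicated probe ids
#'   allowed.
#' @param probe_map Data frame with columns `probe` and `gene` (additional
#'   columns ignored).
#' @return Gene-level fold-change matrix with one row per mapped gene.
#' @export
#' @examples
#' m <- matrix(c(1, 3), 2, 1, dimnames = list(c("p1", "p2"), "C001"))
#' collapse_probes(m, data.frame(probe = c("p1", "p2"), gene = "GENE"))
collapse_probes <- function(x, probe_map) {
  # probe identifiers are platform ids, not gene symbols: matched verbatim
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("probe matrix needs probe row names and condition column names")
  }
  if (!all(c("probe", "gene") %in% names(probe_map))) {
    stop("probe_map needs columns 'probe' and 'gene'")
  }
  map <- unique(data.frame(probe = as.character(probe_map$probe),
                           gene = toupper(as.character(probe_map$gene)),
                           stringsAsFactors = FALSE))
  dup <- unique(map$probe[duplicated(map$probe)])
  if (length(dup) > 0) {
    stop("ambiguous mapping: probe(s) mapped to more than one gene: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  gene <- map$gene[match(rownames(x), map$probe)]
  keep <- !is.na(gene)
  if (!any(keep)) stop("no probe in the matrix is covered by probe_map")
  x <- x[keep, , drop = FALSE]
  gene <- gene[keep]
  vals <- x
  vals[is.na(vals)] <- 0
  sums <- rowsum(vals, gene)
  counts <- rowsum((!is.na(x)) + 0, gene)
  out <- sums / counts
  out[counts == 0] <- NA_real_
  as_fc_matrix(out)
}
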