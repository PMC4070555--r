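#' Protein-interaction graphs
#'
#' A minimal undirected interaction graph: gene symbols as nodes and
#' deduplicated, self-loop-free unordered edges, with precomputed
#' neighbor lists. This is all the annotation-extension step needs.
#'
#' @param edges Two-column data frame or matrix of interacting gene pairs.
#' @return An object of class `interaction_graph`: list with `nodes`
#'   (character), `edges` (two-column data frame) and `neighbors` (named
#'   list of character vectors).
#' @export
interaction_graph <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) stop("edge list needs two columns (geneA, geneB)")
  a <- toupper(as.character(edges[[1]]))
  b <- toupper(as.character(edges[[2]]))
  keep <- !is.na(a) & !is.na(b) & a != "" & b != "" & a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  lo <- lo[dup == FALSE]; hi <- hi[dup == FALSE]
  nodes <- sort(unique(c(lo, hi)))
  nb <- split(c(hi, lo), factor(c(lo, hi), levels = nodes))
  structure(
    list(
      nodes = nodes,
      edges = data.frame(geneA = lo, geneB = hi, stringsAsFactors = FALSE),
      neighbors = lapply(nb, unique)
    ),
    class = "interaction_graph"
  )
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("interaction_graph:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' @rdname interaction_graph
#' @param path Two-column TSV edge list (no header).
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  interaction_graph(df)
}

#' @rdname interaction_graph
#' @param graph An `interaction_graph`.
#' @export
write_interactions <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Neighbors of a gene in an interaction graph
#'
#' @param graph An `interaction_graph`.
#' @param gene A gene symbol.
#' @return Character vector of interaction partners (empty if the gene is
#'   not in the graph).
#' @export
graph_neighbors <- function(graph, gene) {
  stopifnot(inherits(graph, "interaction_graph"))
  graph$neighbors[[toupper(gene)]] %||% character(0)
}

#' Guilt-by-association annotation extension
#'
#' Many genes carry no GO/KEGG annotation, so their regulation cannot be
#' mined from annotation gene sets. Annotations are therefore transferred
#' through interaction neighborhoods: for each gene `g` with at least one
#' interactor, and each functional set `F` not already containing `g`, the
#' overlap between the interactor set `L` of `g` and `F` is tested with
#' the inclusive upper-tail hypergeometric distribution over the transfer
#' universe; when the (uncorrected) p-value is at most `p0`, `g` gains the
#' annotation `F`. A single extension round is performed and original
#' annotations are always retained.
#'
#' @param funcs Functional `gene_set_collection`.
#' @param graph An `interaction_graph`.
#' @param p0 Transfer threshold on the overlap p-value (default `1e-4`).
#' @param universe Transfer universe; default is the union of the graph's
#'   nodes and all annotated genes.
#' @return List with `collection` (the extended copy) and `transfers`, a
#'   data frame of tested (gene, set) pairs with a non-empty neighborhood
#'   overlap: `gene`, `func_name`, `neighborhood_size`, `overlap_size`,
#'   `p_value`, `accepted` (`p_value <= p0`).
#' @export
extend_annotations <- function(funcs, graph, p0 = 1e-4, universe = NULL) {
  stopifnot(inherits(funcs, "gene_set_collection"),
            inherits(graph, "interaction_graph"))
  if (length(graph$nodes) == 0) stop("empty interaction graph")
  if (p0 < 0 || p0 > 1) stop("p0 must be in [0, 1]")
  if (is.null(universe)) {
    universe <- union(graph$nodes, collection_universe(funcs))
  }
  universe <- unique(toupper(universe))
  N <- length(universe)
  Fm <- membership_matrix(funcs, universe)
  K <- colSums(Fm)
  rows <- vector("list", length(graph$nodes))
  for (gi in seq_along(graph$nodes)) {
    g <- graph$nodes[gi]
    L <- intersect(graph$neighbors[[g]], universe)
    nL <- length(L)
    if (nL == 0) next
    x <- colSums(Fm[match(L, universe), , drop = FALSE])
    already <- if (g %in% universe) Fm[match(g, universe), ] > 0 else
      rep(FALSE, ncol(Fm))
    test <- which(x >= 1 & !already)
    if (length(test) == 0) next
    p <- hypergeom_tail(N, K[test], nL, x[test])
    rows[[gi]] <- data.frame(
      gene = g, func_name = funcs$info$name[test],
      neighborhood_size = nL, overlap_size = as.integer(x[test]),
      p_value = p, accepted = p <= p0, stringsAsFactors = FALSE
    )
  }
  transfers <- do.call(rbind, rows) %||% data.frame(
    gene = character(0), func_name = character(0),
    neighborhood_size = integer(0), overlap_size = integer(0),
    p_value = numeric(0), accepted = logical(0), stringsAsFactors = FALSE
  )
  rownames(transfers) <- NULL
  sets <- funcs$sets
  acc <- transfers[transfers$accepted, , drop = FALSE]
  if (nrow(acc) > 0) {
    add <- split(acc$gene, acc$func_name)
    for (nm in names(add)) {
      sets[[nm]] <- unique(c(sets[[nm]], add[[nm]]))
    }
  }
  extended <- gene_set_collection(sets,
    category = funcs$info$category, tf_label = funcs$info$tf_label,
    description = funcs$info$description
  )
  list(collection = extended, transfers = transfers)
}
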