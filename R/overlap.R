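#' Upper-tail hypergeometric overlap probability
#'
#' Probability of observing at least `x` category members when drawing `n`
#' genes without replacement from a universe of `N` genes of which `K`
#' belong to the category: `P(X >= x)` for
#' `X ~ Hypergeometric(N, K, n)`, tail inclusive of `x`. This is the
#' standard enrichment p-value for the overlap of two gene sets.
#'
#' @param N Universe size.
#' @param K Category (first set) size, `K <= N`.
#' @param n Draw (second set) size, `n <= N`.
#' @param x Observed overlap, `0 <= x <= min(K, n)`.
#' @return Numeric vector of upper-tail probabilities (arguments are
#'   recycled to a common length).
#' @export
#' @examples
#' hypergeom_tail(N = 10, K = 5, n = 5, x = 5) # 1 / choose(10, 5)
hypergeom_tail <- function(N, K, n, x) {
  len <- max(length(N), length(K), length(n), length(x))
  N <- rep_len(N, len); K <- rep_len(K, len)
  n <- rep_len(n, len); x <- rep_len(x, len)
  if (any(N < 0 | K < 0 | n < 0 | x < 0) || any(K > N) || any(n > N) ||
      any(x > pmin(K, n))) {
    stop("require 0 <= x <= min(K, n) and K, n <= N")
  }
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted p-values `q_(i) = min_{j >= i}(p_(j) * m / j)`,
#' capped at 1 and returned in input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
bh_qvalues <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Overlap significance for every TFBS x functional pair (criterion A)
#'
#' Computes the inclusive upper-tail hypergeometric p-value for the
#' overlap of every (TFBS set, functional set) pair over a shared gene
#' universe, adjusts across the full family of tested pairs by
#' Benjamini-Hochberg, and returns the pairs with `q <= q_max` and a
#' non-empty overlap. The overlapping genes of a retained pair are the
#' TF's candidate targets for that function.
#'
#' @param tfbs,funcs `gene_set_collection`s (already size-filtered).
#' @param universe Character vector of gene symbols defining the test
#'   universe; defaults to the union of all member genes of both
#'   collections. Sets are restricted to the universe before testing.
#' @param q_max FDR threshold on the pair q-value (default 0.02).
#' @return A data frame with one row per retained pair: `tfbs_name`,
#'   `tf_label`, `func_name`, `universe_size`, `tfbs_size`, `func_size`,
#'   `overlap_size`, `p_value`, `q_value`, and a list column
#'   `overlap_genes`. The number of pairs tested (the BH family size) is
#'   attached as attribute `n_tested`.
#' @export
all_pairwise_overlaps <- function(tfbs, funcs, universe = NULL, q_max = 0.02) {
  stopifnot(inherits(tfbs, "gene_set_collection"),
            inherits(funcs, "gene_set_collection"))
  if (is.null(universe)) {
    universe <- union(collection_universe(tfbs), collection_universe(funcs))
  }
  universe <- unique(toupper(universe))
  if (length(universe) == 0) stop("empty gene universe")
  if (length(tfbs) == 0 || length(funcs) == 0) {
    stop("both collections must contain at least one set")
  }
  Mt <- membership_matrix(tfbs, universe)
  Mf <- membership_matrix(funcs, universe)
  X <- crossprod(Mt, Mf) # overlap counts, tfbs x funcs
  N <- length(universe)
  K <- colSums(Mt)
  n <- colSums(Mf)
  St <- length(tfbs); Sf <- length(funcs)
  p <- hypergeom_tail(N, rep(K, times = Sf), rep(n, each = St), as.vector(X))
  q <- bh_qvalues(p)
  keep <- which(q <= q_max & as.vector(X) >= 1)
  ti <- ((keep - 1) %% St) + 1
  fj <- ((keep - 1) %/% St) + 1
  out <- data.frame(
    tfbs_name = tfbs$info$name[ti],
    tf_label = tfbs$info$tf_label[ti],
    func_name = funcs$info$name[fj],
    universe_size = rep_len(N, length(keep)),
    tfbs_size = K[ti],
    func_size = n[fj],
    overlap_size = as.vector(X)[keep],
    p_value = p[keep],
    q_value = q[keep],
    stringsAsFactors = FALSE
  )
  out$overlap_genes <- lapply(seq_along(keep), function(r) {
    universe[Mt[, ti[r]] > 0 & Mf[, fj[r]] > 0]
  })
  ord <- order(out$tfbs_name, out$func_name)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$pair_id <- paste(out$tfbs_name, out$func_name, sep = "|")
  attr(out, "n_tested") <- St * Sf
  out
}

# 0/1 membership matrix, genes (universe) x sets
membership_matrix <- function(collection, universe) {
  M <- matrix(0, nrow = length(universe), ncol = length(collection),
              dimnames = list(universe, collection$info$name))
  for (i in seq_along(collection$sets)) {
    idx <- match(collection$sets[[i]], universe)
    M[idx[!is.na(idx)], i] <- 1
  }
  M
}
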