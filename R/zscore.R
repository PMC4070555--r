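#' Gene-randomization z-statistic for one set in one condition
#'
#' Many fold-change profiles come from experiments with too few samples
#' for sample permutation, so set-level expression change is assessed
#' against the per-condition gene population: with `m` the mean
#' fold-change over the measured member genes, `mu` and `s` the mean and
#' sample standard deviation over all measured genes in the condition, and
#' `n` the number of measured members,
#' `z = (m - mu) * sqrt(n) / s`, with a two-sided standard-normal p-value
#' (activation and repression are both of interest).
#'
#' @param values Named numeric vector: fold-changes of all genes for one
#'   condition (`NA` = not measured).
#' @param members Character vector of member gene symbols.
#' @return A list with `z`, `p_value` and `n_measured`, or `NULL` when no
#'   member gene is measured (no statistic is emitted).
#' @export
set_zscore <- function(values, members) {
  if (is.null(names(values))) stop("'values' must be named by gene")
  measured <- values[!is.na(values)]
  if (length(measured) < 2) stop("need >= 2 measured genes in the condition")
  s <- stats::sd(measured)
  if (s == 0) stop("zero overall variance: z-statistic undefined")
  mvals <- measured[names(measured) %in% toupper(members)]
  n <- length(mvals)
  if (n == 0) return(NULL)
  z <- (mean(mvals) - mean(measured)) * sqrt(n) / s
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), n_measured = n)
}

# Vectorized z-statistics for a membership matrix (genes x sets) against a
# fold-change matrix (same genes x conditions). Returns sets x conditions
# matrices of z, p and measured-member counts; entries with zero measured
# members are NA. Conditions with < 2 measured genes or zero variance get
# all-NA columns (callers warn).
set_zscore_matrix <- function(M, fc) {
  stopifnot(nrow(M) == nrow(fc))
  W <- (!is.na(fc)) + 0
  V <- fc
  V[is.na(V)] <- 0
  n_cond <- colSums(W)
  gm <- colSums(V) / n_cond
  gvar <- (colSums(V * V) - n_cond * gm^2) / (n_cond - 1)
  gsd <- sqrt(pmax(gvar, 0))
  ok <- n_cond >= 2 & gsd > 0
  cnt <- crossprod(M, W)            # sets x conditions measured members
  mu <- crossprod(M, V) / cnt       # NaN where cnt == 0
  z <- sweep(sweep(mu, 2, gm, "-") * sqrt(cnt), 2, gsd, "/")
  z[cnt == 0] <- NA_real_
  z[, !ok] <- NA_real_
  list(z = z, p = 2 * stats::pnorm(-abs(z)), n = cnt, cond_ok = ok)
}

#' Per-condition expression screen of retained pairs (criterion B)
#'
#' For every condition of the fold-change matrix, computes the
#' gene-randomization z-statistic for each distinct TFBS set, functional
#' set and overlap set appearing among the retained pairs, converts
#' p-values to Benjamini-Hochberg q-values within the condition (three
#' separate families: overlap sets, TFBS sets, functional sets), and marks
#' a (pair, condition) as activated when the overlap set is significant
#' while neither parent set is:
#' `q(overlap) <= q_sig` and `q(TFBS) > q_nonsig` and
#' `q(functional) > q_nonsig`. Expression change must be pronounced in the
#' intersection compared to the two individual sets.
#'
#' @param overlaps Output of [all_pairwise_overlaps()].
#' @param fc Gene-level fold-change matrix (see [as_fc_matrix()]).
#' @param tfbs,funcs The collections the pairs were drawn from.
#' @param q_sig Significance threshold on the overlap q-value
#'   (default 0.02).
#' @param q_nonsig Non-significance threshold on the parent-set q-values
#'   (default 0.05).
#' @return A data frame with one row per (pair, condition): `pair_id`,
#'   `tfbs_name`, `func_name`, `condition`, `n_measured` (overlap members
#'   measured), `z_overlap`, `p_overlap`, `q_overlap`, `z_tfbs`, `q_tfbs`,
#'   `z_func`, `q_func`, `activated`. Conditions with fewer than two
#'   measured genes (or zero variance) are skipped with a warning.
#' @export
condition_screen <- function(overlaps, fc, tfbs, funcs,
                             q_sig = 0.02, q_nonsig = 0.05) {
  stopifnot(is.data.frame(overlaps), nrow(overlaps) > 0)
  fc <- as_fc_matrix(fc)
  if (ncol(fc) < 1) stop("fold-change matrix has no conditions")
  genes <- rownames(fc)

  ut <- unique(overlaps$tfbs_name)
  uf <- unique(overlaps$func_name)
  Mt <- membership_matrix(tfbs[ut], genes)
  Mf <- membership_matrix(funcs[uf], genes)
  Mo <- matrix(0, nrow = length(genes), ncol = nrow(overlaps))
  for (r in seq_len(nrow(overlaps))) {
    idx <- match(overlaps$overlap_genes[[r]], genes)
    Mo[idx[!is.na(idx)], r] <- 1
  }

  zo <- set_zscore_matrix(Mo, fc)
  zt <- set_zscore_matrix(Mt, fc)
  zf <- set_zscore_matrix(Mf, fc)
  if (any(!zo$cond_ok)) {
    warning("skipping condition(s) with < 2 measured genes or zero variance: ",
            paste(colnames(fc)[!zo$cond_ok], collapse = ", "))
  }
  qcol <- function(P) {
    Q <- P
    for (j in seq_len(ncol(P))) {
      ok <- !is.na(P[, j])
      Q[ok, j] <- bh_qvalues(P[ok, j])
    }
    Q
  }
  qo <- qcol(zo$p); qt <- qcol(zt$p); qf <- qcol(zf$p)

  it <- match(overlaps$tfbs_name, ut)
  jf <- match(overlaps$func_name, uf)
  C <- ncol(fc)
  P <- nrow(overlaps)
  cond <- rep(colnames(fc), each = P)
  ridx <- rep(seq_len(P), times = C)
  flat <- function(M, rows) as.vector(M[rows, , drop = FALSE])
  out <- data.frame(
    pair_id = overlaps$pair_id[ridx],
    tfbs_name = overlaps$tfbs_name[ridx],
    func_name = overlaps$func_name[ridx],
    condition = cond,
    n_measured = flat(zo$n, seq_len(P)),
    z_overlap = flat(zo$z, seq_len(P)),
    p_overlap = flat(zo$p, seq_len(P)),
    q_overlap = flat(qo, seq_len(P)),
    z_tfbs = flat(zt$z, it),
    q_tfbs = flat(qt, it),
    z_func = flat(zf$z, jf),
    q_func = flat(qf, jf),
    stringsAsFactors = FALSE
  )
  out$activated <- !is.na(out$q_overlap) & !is.na(out$q_tfbs) & !is.na(out$q_func) &
    out$q_overlap <= q_sig & out$q_tfbs > q_nonsig & out$q_func > q_nonsig
  out
}

#' Write a condition screen in long format
#'
#' One row per (pair, condition, set role) with the role-specific
#' statistic, mirroring the three z-tests behind each activation call.
#'
#' @param screened Output of [condition_screen()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(screened, path) {
  role <- function(r, z, q) data.frame(
    pair_id = screened$pair_id, condition = screened$condition,
    set_role = r, n_measured = screened$n_measured,
    z = z, q = q, activated = screened$activated, stringsAsFactors = FALSE
  )
  long <- rbind(
    role("overlap", screened$z_overlap, screened$q_overlap),
    role("tfbs", screened$z_tfbs, screened$q_tfbs),
    role("func", screened$z_func, screened$q_func)
  )
  long <- long[order(long$pair_id, long$condition, long$set_role), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
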