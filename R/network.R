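#' Assemble association records and context triples (criterion C)
#'
#' A (TFBS set, functional set) pair with an activated expression pattern
#' in at least `k` conditions becomes an association record; each
#' (retained pair, activated condition) becomes one context triple
#' (TF, functional set, condition) — the atomic output of the mining run.
#'
#' @param screened Output of [condition_screen()].
#' @param overlaps Output of [all_pairwise_overlaps()] (source of the
#'   overlap genes and criterion-A q-value for each pair).
#' @param k Minimum number of supporting conditions (default 10).
#' @return A list with two data frames. `records`: one row per retained
#'   pair with `tfbs_name`, `tf_label`, `func_name`, `overlap_size`,
#'   `overlap_q` (criterion A), list columns `overlap_genes` and
#'   `supporting_conditions`, and `n_conditions`. `triples`: one row per
#'   (retained pair, activated condition) with the per-condition overlap
#'   z and expression q-value. `sum(records$n_conditions) == nrow(triples)`.
#' @export
assemble_network <- function(screened, overlaps, k = 10) {
  stopifnot(is.data.frame(screened), is.data.frame(overlaps))
  if (k < 1) stop("k must be >= 1")
  act <- screened[screened$activated, , drop = FALSE]
  counts <- table(act$pair_id)
  keep_ids <- names(counts)[counts >= k]
  ridx <- match(keep_ids, overlaps$pair_id)
  stopifnot(!anyNA(ridx))
  ridx <- sort(ridx) # deterministic: pair order of the overlap table
  records <- data.frame(
    pair_id = overlaps$pair_id[ridx],
    tfbs_name = overlaps$tfbs_name[ridx],
    tf_label = overlaps$tf_label[ridx],
    func_name = overlaps$func_name[ridx],
    overlap_size = overlaps$overlap_size[ridx],
    overlap_q = overlaps$q_value[ridx],
    stringsAsFactors = FALSE
  )
  records$overlap_genes <- overlaps$overlap_genes[ridx]
  records$supporting_conditions <- lapply(records$pair_id, function(id) {
    act$condition[act$pair_id == id]
  })
  records$n_conditions <- lengths(records$supporting_conditions)

  tri <- act[act$pair_id %in% records$pair_id, , drop = FALSE]
  tri <- tri[order(match(tri$pair_id, records$pair_id), tri$condition), ]
  triples <- data.frame(
    tf_label = records$tf_label[match(tri$pair_id, records$pair_id)],
    tfbs_name = tri$tfbs_name,
    func_name = tri$func_name,
    condition = tri$condition,
    z_overlap = tri$z_overlap,
    q_overlap_expression = tri$q_overlap,
    stringsAsFactors = FALSE
  )
  rownames(records) <- rownames(triples) <- NULL
  list(records = records, triples = triples)
}

#' Select high fold-change candidate targets
#'
#' Within each association record, individual candidate targets are the
#' overlap genes that show strong expression change (absolute linear fold
#' change of `fc_threshold` or higher, i.e. `|log2FC| >= log2(fc_threshold)`)
#' across enough conditions: at least `ceiling(frac * k)` by default, or
#' strictly more than `frac * k` when `strict = TRUE`. Counting is
#' restricted to the record's supporting conditions (`scope = "supporting"`,
#' the context-specific reading) or may span the whole compendium
#' (`scope = "all"`).
#'
#' @param records `records` data frame from [assemble_network()].
#' @param fc Gene-level log2 fold-change matrix.
#' @param fc_threshold Linear fold-change cutoff (default 1.5).
#' @param frac Fraction of `k` conditions required (default 0.3).
#' @param k The minimum-condition parameter the run used (default 10).
#' @param strict Use the strict reading `count > frac * k`.
#' @param scope Conditions counted: `"supporting"` (default) or `"all"`.
#' @return Data frame with one row per (record, overlap gene): `gene`,
#'   `tf_label`, `tfbs_name`, `func_name`, `n_highfc_conditions`,
#'   `measured`, `passed`. Genes absent from the matrix count zero
#'   high-FC conditions and are flagged `measured = FALSE`.
#' @export
select_candidate_targets <- function(records, fc, fc_threshold = 1.5,
                                     frac = 0.3, k = 10, strict = FALSE,
                                     scope = c("supporting", "all")) {
  scope <- match.arg(scope)
  stopifnot(is.data.frame(records))
  fc <- as_fc_matrix(fc)
  if (fc_threshold < 1) stop("fc_threshold is a linear fold change, >= 1")
  cut <- log2(fc_threshold)
  required <- if (strict) floor(frac * k + 1e-9) + 1 else ceiling(frac * k - 1e-9)
  out <- lapply(seq_len(nrow(records)), function(r) {
    genes <- records$overlap_genes[[r]]
    conds <- if (scope == "supporting") {
      records$supporting_conditions[[r]]
    } else {
      colnames(fc)
    }
    gi <- match(genes, rownames(fc))
    cnt <- integer(length(genes))
    measured <- !is.na(gi)
    if (any(measured) && length(conds) > 0) {
      sub <- abs(fc[gi[measured], conds, drop = FALSE]) >= cut
      cnt[measured] <- rowSums(sub, na.rm = TRUE)
    }
    data.frame(
      gene = genes, tf_label = records$tf_label[r],
      tfbs_name = records$tfbs_name[r], func_name = records$func_name[r],
      n_highfc_conditions = cnt, measured = measured,
      passed = cnt >= required, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out) %||% data.frame(
    gene = character(0), tf_label = character(0), tfbs_name = character(0),
    func_name = character(0), n_highfc_conditions = integer(0),
    measured = logical(0), passed = logical(0), stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Pool a TF's context-specific targets
#'
#' Union, over all of a TF's association records (across its TFBS sets,
#' including any `_all` union set), of the candidate targets that passed
#' the high fold-change rule. This pooled set is the TF-level prediction
#' used for gold-standard evaluation.
#'
#' @param records `records` data frame from [assemble_network()].
#' @param targets Output of [select_candidate_targets()].
#' @param tf A TF label.
#' @return Character vector of pooled predicted target genes (empty, with
#'   a warning, for a TF with no retained record).
#' @export
pool_tf_targets <- function(records, targets, tf) {
  if (!tf %in% records$tf_label) {
    warning("no association record for TF: ", tf)
    return(character(0))
  }
  sort(unique(targets$gene[targets$passed & !is.na(targets$tf_label) &
                             targets$tf_label == tf]))
}

#' Write mining outputs as TSV / JSON artifacts
#'
#' `write_network_tsvs` writes the association records (conditions
#' semicolon-joined), triples and targets tables; `write_network_json`
#' writes a typed node/edge network document (TF and function nodes,
#' `tf->func` association edges, `tf->gene` target edges).
#'
#' @param net List from [assemble_network()].
#' @param targets Output of [select_candidate_targets()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_network_tsvs <- function(net, targets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- net$records
  flat <- data.frame(
    tfbs_name = rec$tfbs_name, tf_label = rec$tf_label,
    func_name = rec$func_name, overlap_size = rec$overlap_size,
    overlap_q = rec$overlap_q,
    n_conditions = rec$n_conditions,
    supporting_conditions = vapply(rec$supporting_conditions, paste,
                                   character(1), collapse = ";"),
    overlap_genes = vapply(rec$overlap_genes, paste, character(1),
                           collapse = ";"),
    stringsAsFactors = FALSE
  )
  paths <- file.path(dir, c("associations.tsv", "triples.tsv", "targets.tsv"))
  utils::write.table(flat, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(net$triples, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(targets, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' @rdname write_network_tsvs
#' @param path Output JSON path.
#' @export
write_network_json <- function(net, targets, path) {
  rec <- net$records
  passed <- targets[targets$passed, , drop = FALSE]
  doc <- list(
    nodes = list(
      tfs = sort(unique(rec$tf_label[!is.na(rec$tf_label)])),
      functions = sort(unique(rec$func_name)),
      genes = sort(unique(passed$gene))
    ),
    edges = list(
      tf_func = data.frame(
        tf = rec$tf_label, func = rec$func_name, tfbs_set = rec$tfbs_name,
        n_conditions = rec$n_conditions, stringsAsFactors = FALSE
      ),
      tf_gene = unique(data.frame(
        tf = passed$tf_label, gene = passed$gene, stringsAsFactors = FALSE
      ))
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Heat-map matrix for one association record
#'
#' The display behind each mined association: overlap genes by supporting
#' conditions, log2 fold-change values (genes absent from the matrix give
#' `NA` rows).
#'
#' @param record One-row slice of the `records` data frame.
#' @param fc Gene-level fold-change matrix.
#' @return Numeric matrix, overlap genes x supporting conditions.
#' @export
record_heatmap_matrix <- function(record, fc) {
  stopifnot(nrow(record) == 1)
  fc <- as_fc_matrix(fc)
  genes <- record$overlap_genes[[1]]
  conds <- record$supporting_conditions[[1]]
  m <- matrix(NA_real_, length(genes), length(conds),
              dimnames = list(genes, conds))
  gi <- match(genes, rownames(fc))
  m[!is.na(gi), ] <- fc[gi[!is.na(gi)], conds, drop = FALSE]
  m
}
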