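#' Pipeline configuration
#'
#' All user-tunable thresholds of the mining pipeline, each with its
#' documented default: overlap FDR `q_overlap = 0.02` (criterion A),
#' overlap-expression FDR `q_expr = 0.02` and parent-set non-significance
#' cutoff `q_parent = 0.05` (criterion B), minimum supporting conditions
#' `k = 10` (criterion C), candidate-target rule `fc_threshold = 1.5`
#' (linear fold change) across `frac = 0.3` of `k` conditions, annotation
#' transfer threshold `p0 = 1e-4`, and gene-set size bounds 10-500.
#'
#' @param q_overlap FDR threshold on pair overlap q-values.
#' @param q_expr FDR threshold on the overlap-set expression q-value.
#' @param q_parent Parent sets must have expression q-values above this.
#' @param k Minimum number of supporting conditions.
#' @param fc_threshold Linear fold-change cutoff for candidate targets.
#' @param frac Fraction of `k` conditions a candidate target must pass.
#' @param p0 Annotation-extension transfer p-value threshold.
#' @param min_set,max_set Gene-set size bounds.
#' @param strict_frac Use the strict `count > frac * k` reading of the
#'   target rule instead of `count >= ceiling(frac * k)`.
#' @param highfc_scope Count target high-FC conditions among the record's
#'   `"supporting"` conditions (default) or `"all"` conditions.
#' @param add_tf_unions Append per-TF `_all` union sets before mining.
#' @return A validated list of class `regnet_config`.
#' @export
regnet_config <- function(q_overlap = 0.02, q_expr = 0.02, q_parent = 0.05,
                          k = 10, fc_threshold = 1.5, frac = 0.3, p0 = 1e-4,
                          min_set = 10, max_set = 500, strict_frac = FALSE,
                          highfc_scope = c("supporting", "all"),
                          add_tf_unions = TRUE) {
  highfc_scope <- match.arg(highfc_scope)
  chk01 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v > 1) {
      stop("'", nm, "' must be a single value in (0, 1]")
    }
  }
  chk01(q_overlap, "q_overlap"); chk01(q_expr, "q_expr")
  chk01(q_parent, "q_parent")
  if (!is.numeric(p0) || p0 < 0 || p0 > 1) stop("'p0' must be in [0, 1]")
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1) {
    stop("'k' must be >= 1")
  }
  if (fc_threshold < 1) stop("'fc_threshold' must be >= 1 (linear fold change)")
  if (frac <= 0 || frac > 1) stop("'frac' must be in (0, 1]")
  if (min_set < 1 || max_set < min_set) stop("invalid gene-set size bounds")
  structure(
    list(q_overlap = q_overlap, q_expr = q_expr, q_parent = q_parent,
         k = as.integer(k), fc_threshold = fc_threshold, frac = frac, p0 = p0,
         min_set = as.integer(min_set), max_set = as.integer(max_set),
         strict_frac = isTRUE(strict_frac), highfc_scope = highfc_scope,
         add_tf_unions = isTRUE(add_tf_unions)),
    class = "regnet_config"
  )
}

#' @rdname regnet_config
#' @param path YAML file whose keys mirror the `regnet_config` arguments.
#' @param ... Overrides applied on top of the file values.
#' @export
regnet_config_from_yaml <- function(path, ...) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files")
  }
  vals <- yaml::read_yaml(path)
  dots <- list(...)
  vals[names(dots)] <- dots
  known <- names(formals(regnet_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(regnet_config, vals)
}

#' Run the full context-specific transcription-network mining pipeline
#'
#' Orchestrates: preprocessing (universe construction, optional
#' guilt-by-association annotation extension, size filtering, per-TF
#' union sets) -> pairwise overlap testing (criterion A) -> per-condition
#' expression screening (criterion B) -> association/triple assembly
#' (criterion C) -> candidate-target selection. The analysis universe is
#' the union of all member genes of both collections intersected with the
#' genes measured in the fold-change matrix.
#'
#' @param tfbs TFBS `gene_set_collection`.
#' @param funcs Functional `gene_set_collection`.
#' @param fc Gene-level log2 fold-change matrix (see [as_fc_matrix()]).
#' @param config A [regnet_config()].
#' @param ppi Optional `interaction_graph`; when supplied, functional
#'   annotations are extended through interaction neighborhoods (at
#'   `config$p0`) before mining.
#' @param out_dir Optional directory; when given, all result tables, the
#'   network JSON and a run manifest are written there.
#' @return A list of class `regnet_result`: `overlaps`, `screened`,
#'   `records`, `triples`, `targets`, `transfers` (annotation transfers or
#'   `NULL`), `universe`, `config` and `manifest` (per-stage counts).
#' @export
run_regnet <- function(tfbs, funcs, fc, config = regnet_config(), ppi = NULL,
                       out_dir = NULL) {
  stopifnot(inherits(config, "regnet_config"))
  fc <- as_fc_matrix(fc)
  transfers <- NULL
  if (!is.null(ppi)) {
    ext <- extend_annotations(funcs, ppi, p0 = config$p0)
    funcs <- ext$collection
    transfers <- ext$transfers
  }
  universe <- intersect(
    union(collection_universe(tfbs), collection_universe(funcs)),
    rownames(fc)
  )
  if (length(universe) == 0) {
    stop("stage geneset_io: no gene is shared between the collections and ",
         "the fold-change matrix")
  }
  tfbs_f <- filter_by_size(tfbs, config$min_set, config$max_set, universe)
  funcs_f <- filter_by_size(funcs, config$min_set, config$max_set, universe)
  if (config$add_tf_unions) {
    tfbs_f <- build_tf_union_sets(tfbs_f)
    # unions are exempt from the max-size cap but must stay measurable
    tfbs_f <- filter_by_size(tfbs_f, config$min_set,
                             max_size = .Machine$integer.max,
                             universe = universe)
  }
  if (length(tfbs_f) == 0 || length(funcs_f) == 0) {
    stop("stage geneset_io: no gene set left after size filtering")
  }
  overlaps <- all_pairwise_overlaps(tfbs_f, funcs_f, universe,
                                    q_max = config$q_overlap)
  empty <- nrow(overlaps) == 0
  if (empty) {
    screened <- NULL
    net <- list(
      records = data.frame(pair_id = character(0), tfbs_name = character(0),
                           tf_label = character(0), func_name = character(0),
                           overlap_size = integer(0), overlap_q = numeric(0),
                           n_conditions = integer(0)),
      triples = data.frame(tf_label = character(0), tfbs_name = character(0),
                           func_name = character(0), condition = character(0),
                           z_overlap = numeric(0),
                           q_overlap_expression = numeric(0))
    )
    net$records$overlap_genes <- list()
    net$records$supporting_conditions <- list()
    targets <- select_candidate_targets(net$records, fc,
                                        config$fc_threshold, config$frac,
                                        config$k, config$strict_frac,
                                        config$highfc_scope)
  } else {
    screened <- condition_screen(overlaps, fc, tfbs_f, funcs_f,
                                 q_sig = config$q_expr,
                                 q_nonsig = config$q_parent)
    net <- assemble_network(screened, overlaps, k = config$k)
    targets <- select_candidate_targets(net$records, fc,
                                        config$fc_threshold, config$frac,
                                        config$k, config$strict_frac,
                                        config$highfc_scope)
  }
  manifest <- list(
    config = unclass(config),
    counts = list(
      universe_genes = length(universe),
      tfbs_sets = length(tfbs_f),
      func_sets = length(funcs_f),
      conditions = ncol(fc),
      pairs_tested = attr(overlaps, "n_tested"),
      pairs_retained = nrow(overlaps),
      annotation_transfers = if (is.null(transfers)) NULL else
        sum(transfers$accepted),
      records = nrow(net$records),
      triples = nrow(net$triples),
      targets_passed = sum(targets$passed)
    )
  )
  stopifnot(sum(net$records$n_conditions) == nrow(net$triples),
            nrow(net$records) <= nrow(overlaps))
  res <- structure(
    list(overlaps = overlaps, screened = screened, records = net$records,
         triples = net$triples, targets = targets, transfers = transfers,
         universe = universe, config = config, manifest = manifest),
    class = "regnet_result"
  )
  if (!is.null(out_dir)) write_regnet_result(res, out_dir)
  res
}

#' @export
print.regnet_result <- function(x, ...) {
  cnt <- x$manifest$counts
  cat("regnet mining result\n")
  cat(sprintf("  universe: %d genes, %d conditions\n",
              cnt$universe_genes, cnt$conditions))
  cat(sprintf("  criterion A: %d of %d pairs retained (q <= %g)\n",
              cnt$pairs_retained, cnt$pairs_tested, x$config$q_overlap))
  cat(sprintf("  criteria B+C: %d association records, %d context triples (k >= %d)\n",
              cnt$records, cnt$triples, x$config$k))
  cat(sprintf("  candidate targets passing the high fold-change rule: %d\n",
              cnt$targets_passed))
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#'
#' Writes the overlap table, the long-format condition screen, the
#' association/triple/target tables, the network JSON and a manifest
#' (config echo plus per-stage counts).
#'
#' @param res A `regnet_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_regnet_result <- function(res, dir) {
  stopifnot(inherits(res, "regnet_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ov <- res$overlaps
  ov$overlap_genes <- vapply(ov$overlap_genes, paste, character(1),
                             collapse = ";")
  utils::write.table(ov, file.path(dir, "overlaps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(res$screened)) {
    write_screen_tsv(res$screened, file.path(dir, "screen.tsv"))
  }
  write_network_tsvs(list(records = res$records, triples = res$triples),
                     res$targets, dir)
  write_network_json(list(records = res$records, triples = res$triples),
                     res$targets, file.path(dir, "network.json"))
  if (!is.null(res$transfers)) {
    utils::write.table(res$transfers, file.path(dir, "transfers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
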