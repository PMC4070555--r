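#' Build a pooled gold standard for one TF
#'
#' Context-matched gold standards are rarely available, so evaluation
#' pools: the union of the TF's ChIP target sets (one set per ChIP-seq or
#' ChIP-chip experiment) restricted to the TF's binding-site universe, so
#' that only targets with a known TFBS count as positives.
#'
#' @param chip_target_sets List of character vectors of target genes (or a
#'   `gene_set_collection`).
#' @param tfbs_universe Character vector: genes carrying a binding site
#'   for the TF (the evaluation universe).
#' @return Character vector of gold-standard positives. Warns when empty.
#' @export
build_gold_standard <- function(chip_target_sets, tfbs_universe) {
  if (inherits(chip_target_sets, "gene_set_collection")) {
    chip_target_sets <- chip_target_sets$sets
  }
  stopifnot(is.list(chip_target_sets), length(tfbs_universe) > 0)
  pooled <- unique(toupper(unlist(chip_target_sets, use.names = FALSE)))
  gold <- intersect(pooled, unique(toupper(tfbs_universe)))
  if (length(gold) == 0) {
    warning("empty gold standard after restriction to the TFBS universe; ",
            "evaluation would be degenerate")
  }
  sort(gold)
}

#' Evaluate pooled predictions against a pooled gold standard
#'
#' Contingency evaluation within a TF's binding-site universe of `N`
#' genes: with `K` gold-standard positives, `n` predicted targets and `x`
#' true positives, sensitivity is `x / K`, specificity
#' `((N - K) - (n - x)) / (N - K)`, and the p-value against random
#' prediction is the inclusive upper-tail hypergeometric probability
#' `P(X >= x)`.
#'
#' @param predictions Character vector of predicted target genes
#'   (predictions outside the universe are dropped with a warning).
#' @param gold Character vector of gold-standard positives (must lie in
#'   the universe; violators dropped with a warning).
#' @param universe Character vector: the TF's TFBS gene universe.
#' @param tf_label Optional TF name carried into the result.
#' @return An object of class `tf_evaluation`: list with `tf_label`, `N`,
#'   `K`, `n`, `x`, `sensitivity`, `specificity`, `p_value`, plus the
#'   (restricted) `predictions`, `gold` and `universe`.
#' @export
#' @examples
#' u <- sprintf("G%03d", 1:564)
#' ev <- evaluate_tf(u[c(1:39, 300:325)], u[1:270], u, tf_label = "E2F1")
#' round(c(ev$sensitivity, ev$specificity, ev$p_value), 4)
evaluate_tf <- function(predictions, gold, universe, tf_label = NA_character_) {
  universe <- unique(toupper(universe))
  predictions <- unique(toupper(predictions))
  gold <- unique(toupper(gold))
  if (length(universe) == 0) stop("empty evaluation universe")
  drop_p <- setdiff(predictions, universe)
  if (length(drop_p) > 0) {
    warning(length(drop_p), " prediction(s) outside the universe dropped")
    predictions <- intersect(predictions, universe)
  }
  drop_g <- setdiff(gold, universe)
  if (length(drop_g) > 0) {
    warning(length(drop_g), " gold-standard gene(s) outside the universe dropped")
    gold <- intersect(gold, universe)
  }
  N <- length(universe); K <- length(gold); n <- length(predictions)
  if (K == 0 || K == N) {
    stop("sensitivity/specificity undefined: gold standard covers none or ",
         "all of the universe")
  }
  x <- length(intersect(predictions, gold))
  structure(
    list(
      tf_label = tf_label, N = N, K = K, n = n, x = x,
      sensitivity = x / K,
      specificity = ((N - K) - (n - x)) / (N - K),
      p_value = hypergeom_tail(N, K, n, x),
      predictions = predictions, gold = gold, universe = universe
    ),
    class = "tf_evaluation"
  )
}

#' @export
print.tf_evaluation <- function(x, ...) {
  cat("TF evaluation", if (!is.na(x$tf_label)) paste0("(", x$tf_label, ")"), "\n")
  cat(sprintf("  universe N = %d, positives K = %d, predicted n = %d, true positives x = %d\n",
              x$N, x$K, x$n, x$x))
  cat(sprintf("  sensitivity %.4f, specificity %.4f, hypergeometric p %.4f\n",
              x$sensitivity, x$specificity, x$p_value))
  invisible(x)
}

#' Augment the gold standard with extra validated positives
#'
#' When additional targets are validated (for example by a dedicated ChIP
#' assay) after the pooled gold standard was assembled, they can be added
#' to the positive set: `K' = K + |extra|` and
#' `x' = x + |extra ∩ predictions|`, with `N` and `n` held fixed (the
#' extras were already inside the universe and, where applicable, the
#' prediction set).
#'
#' @param result A `tf_evaluation`.
#' @param extra_positives Character vector of new positives; must lie in
#'   the universe and be disjoint from the current gold standard.
#' @return A recomputed `tf_evaluation`.
#' @export
augment_gold <- function(result, extra_positives) {
  stopifnot(inherits(result, "tf_evaluation"))
  extra <- unique(toupper(extra_positives))
  if (length(extra) == 0) return(result)
  if (!all(extra %in% result$universe)) {
    stop("extra positives must lie inside the evaluation universe")
  }
  if (length(intersect(extra, result$gold)) > 0) {
    stop("extra positives overlap the existing gold standard")
  }
  K <- result$K + length(extra)
  x <- result$x + length(intersect(extra, result$predictions))
  if (K == result$N) stop("augmented gold standard covers the whole universe")
  out <- result
  out$gold <- sort(c(result$gold, extra))
  out$K <- K
  out$x <- x
  out$sensitivity <- x / K
  out$specificity <- ((result$N - K) - (result$n - x)) / (result$N - K)
  out$p_value <- hypergeom_tail(result$N, K, result$n, x)
  out
}

#' Write evaluation results
#'
#' @param results A `tf_evaluation` or list of them.
#' @param tsv,json Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_evaluation <- function(results, tsv = NULL, json = NULL) {
  if (inherits(results, "tf_evaluation")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(tf_label = r$tf_label, N = r$N, K = r$K, n = r$n, x = r$x,
               sensitivity = r$sensitivity, specificity = r$specificity,
               p_value = r$p_value, stringsAsFactors = FALSE)
  }))
  if (!is.null(tsv)) {
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(df, json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(c(tsv, json))
}
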