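#' Planted regulon specification
#'
#' One planted context-specific regulon: TFBS set `tfbs` and functional
#' set `func` are forced to share exactly `overlap_size` genes, and in
#' each condition of `conditions` those overlap genes receive a mean log2
#' fold-change shift of `delta` on top of the background noise, while the
#' non-overlap members of both parent sets receive noise only. Regulons
#' with `delta = 0` are structural decoys: they pass the overlap criterion
#' but carry no expression signal (they populate the multiple-testing
#' families the way unrelated-but-overlapping set pairs do in real
#' annotation collections).
#'
#' @param tfbs,func 1-based indices of the TFBS and functional set.
#' @param overlap_size Number of shared genes.
#' @param conditions Integer indices of the planted conditions.
#' @param delta Mean log2 fold-change shift of the overlap genes.
#' @return A list of class `regnet_regulon`.
#' @export
regulon <- function(tfbs, func, overlap_size = 30, conditions = integer(0),
                    delta = 0) {
  stopifnot(length(tfbs) == 1, length(func) == 1, overlap_size >= 1,
            is.numeric(delta), length(delta) == 1)
  structure(list(tfbs = as.integer(tfbs), func = as.integer(func),
                 overlap_size = as.integer(overlap_size),
                 conditions = as.integer(conditions), delta = delta),
            class = "regnet_regulon")
}

#' Simulation designs
#'
#' A `simulation_design` fixes every parameter of a synthetic study:
#' universe size, numbers and sizes of TFBS and functional gene sets,
#' number of fold-change conditions, the planted regulons, the per-gene
#' log2 fold-change noise (i.i.d. normal, mean 0, sd `noise_sd`), the
#' protein-interaction wiring used for annotation-extension tests, and a
#' seed. `design_null` and `design_recovery` are the two canonical study
#' conditions used for calibration: a signal-free design (2,000 genes,
#' 30 conditions, `delta = 0`) and a genome-scale planted-regulon design
#' in the method's operating regime (20,000 genes; parent sets at the
#' 500-gene size cap; one `delta = 2` regulon with a 30-gene overlap
#' planted in 12 conditions; 100 structural decoy pairs; noise sd 1.8 —
#' see the methods vignette for the power analysis behind these values).
#'
#' @param n_genes Universe size.
#' @param n_tfbs_sets,n_func_sets Numbers of TFBS and functional sets.
#' @param set_size_range Length-2 integer range of set sizes (background
#'   sets are drawn uniformly in the range; planted sets use the maximum).
#' @param n_conditions Number of fold-change conditions.
#' @param regulons List of [regulon()] objects. Each TFBS or functional
#'   set may appear in at most one regulon (so forced overlaps are exact).
#' @param noise_sd Standard deviation of the background log2 fold-change
#'   noise.
#' @param ppi_interactors Interactors wired from each planted target into
#'   its functional set.
#' @param ppi_background_edges Random background PPI edges.
#' @param seed Integer seed making the simulation fully reproducible.
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(n_genes = 2000, n_tfbs_sets = 10,
                              n_func_sets = 20, set_size_range = c(50, 150),
                              n_conditions = 30, regulons = list(),
                              noise_sd = 1, ppi_interactors = 10,
                              ppi_background_edges = n_genes, seed = 1L) {
  stopifnot(n_genes >= 10, n_tfbs_sets >= 1, n_func_sets >= 1,
            length(set_size_range) == 2, set_size_range[1] >= 1,
            set_size_range[2] >= set_size_range[1],
            set_size_range[2] <= n_genes, n_conditions >= 1, noise_sd > 0)
  for (rg in regulons) {
    stopifnot(inherits(rg, "regnet_regulon"))
    if (rg$tfbs < 1 || rg$tfbs > n_tfbs_sets || rg$func < 1 ||
        rg$func > n_func_sets) {
      stop("regulon set index out of range")
    }
    if (rg$overlap_size > set_size_range[1]) {
      stop("infeasible design: planted overlap exceeds the minimum set size")
    }
    if (length(rg$conditions) > 0 &&
        (min(rg$conditions) < 1 || max(rg$conditions) > n_conditions)) {
      stop("regulon condition index out of range")
    }
  }
  ti <- vapply(regulons, `[[`, integer(1), "tfbs")
  fi <- vapply(regulons, `[[`, integer(1), "func")
  if (anyDuplicated(ti) || anyDuplicated(fi)) {
    stop("each TFBS/functional set may appear in at most one regulon")
  }
  structure(
    list(n_genes = as.integer(n_genes), n_tfbs_sets = as.integer(n_tfbs_sets),
         n_func_sets = as.integer(n_func_sets),
         set_size_range = as.integer(set_size_range),
         n_conditions = as.integer(n_conditions), regulons = regulons,
         noise_sd = noise_sd, ppi_interactors = as.integer(ppi_interactors),
         ppi_background_edges = as.integer(ppi_background_edges),
         seed = as.integer(seed)),
    class = "simulation_design"
  )
}

#' @rdname simulation_design
#' @export
design_null <- function(seed = 1L) {
  simulation_design(seed = seed)
}

#' @rdname simulation_design
#' @param delta Effect size of the single signal regulon (the benchmark
#'   default is 2, i.e. a four-fold mean change).
#' @param n_decoys Number of structural decoy pairs.
#' @export
design_recovery <- function(seed = 1L, delta = 2, n_decoys = 100) {
  n_pairs <- 1 + n_decoys
  regs <- c(
    list(regulon(1, 1, overlap_size = 30, conditions = 1:12, delta = delta)),
    lapply(seq_len(n_decoys) + 1L, function(i) {
      regulon(i, i, overlap_size = 30, conditions = integer(0), delta = 0)
    })
  )
  simulation_design(
    n_genes = 20000, n_tfbs_sets = n_pairs + 4L, n_func_sets = n_pairs + 4L,
    set_size_range = c(500, 500), n_conditions = 30, regulons = regs,
    noise_sd = 1.8, seed = seed
  )
}

#' Simulate a full synthetic study
#'
#' Generates, deterministically from `design$seed`: a TFBS collection
#' (one TF per set, labels `TF001...`), a functional collection, a
#' genes-by-conditions log2 fold-change matrix, a protein-interaction
#' graph wiring each planted target to interactors inside its functional
#' set (plus random background edges), and the ground truth. Background
#' set memberships are uniform; each planted regulon forces an overlap of
#' exactly its stated size; in each planted condition the overlap genes
#' get `delta` plus noise while all other genes (including the non-overlap
#' members of the parent sets) get noise only.
#'
#' @param design A [simulation_design()].
#' @return A list of class `regnet_simulation`: `tfbs`, `funcs`
#'   (`gene_set_collection`s), `fc` (matrix), `ppi`
#'   (`interaction_graph`), `truth` (list with data frames `triples` —
#'   the planted (TF, function, condition) triples — and `targets`, plus
#'   `design`).
#' @export
simulate_regnet <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  N <- design$n_genes
  genes <- sprintf("G%06d", seq_len(N))
  conds <- sprintf("C%03d", seq_len(design$n_conditions))
  rng_size <- function() {
    r <- design$set_size_range
    if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1)
  }

  tf_sets <- vector("list", design$n_tfbs_sets)
  fn_sets <- vector("list", design$n_func_sets)
  ov_idx <- vector("list", length(design$regulons))
  for (ri in seq_along(design$regulons)) {
    rg <- design$regulons[[ri]]
    sz_t <- max(rng_size(), rg$overlap_size)
    sz_f <- max(rng_size(), rg$overlap_size)
    idx <- sample.int(N, sz_t + sz_f - rg$overlap_size)
    ov <- idx[seq_len(rg$overlap_size)]
    ov_idx[[ri]] <- ov
    tf_sets[[rg$tfbs]] <- c(ov, idx[rg$overlap_size + seq_len(sz_t - rg$overlap_size)])
    fn_sets[[rg$func]] <- c(ov, idx[sz_t + seq_len(sz_f - rg$overlap_size)])
  }
  for (i in seq_len(design$n_tfbs_sets)) {
    if (is.null(tf_sets[[i]])) tf_sets[[i]] <- sample.int(N, rng_size())
  }
  for (j in seq_len(design$n_func_sets)) {
    if (is.null(fn_sets[[j]])) fn_sets[[j]] <- sample.int(N, rng_size())
  }
  tf_labels <- sprintf("TF%03d", seq_len(design$n_tfbs_sets))
  tfbs <- gene_set_collection(
    stats::setNames(lapply(tf_sets, function(i) genes[i]),
                    sprintf("TFBS%03d", seq_len(design$n_tfbs_sets))),
    category = "TFBS", tf_label = tf_labels,
    description = "simulated TFBS gene set"
  )
  funcs <- gene_set_collection(
    stats::setNames(lapply(fn_sets, function(i) genes[i]),
                    sprintf("FUNC%03d", seq_len(design$n_func_sets))),
    category = "GO_BP", description = "simulated functional gene set"
  )

  fc <- matrix(stats::rnorm(N * design$n_conditions, 0, design$noise_sd),
               N, design$n_conditions, dimnames = list(genes, conds))
  for (ri in seq_along(design$regulons)) {
    rg <- design$regulons[[ri]]
    if (rg$delta != 0 && length(rg$conditions) > 0) {
      fc[ov_idx[[ri]], rg$conditions] <- fc[ov_idx[[ri]], rg$conditions] + rg$delta
    }
  }

  # PPI: wire every planted (signal) target to interactors inside its
  # functional set, then add random background edges.
  edges <- list()
  for (ri in seq_along(design$regulons)) {
    rg <- design$regulons[[ri]]
    if (rg$delta == 0) next
    fmem <- fn_sets[[rg$func]]
    for (g in ov_idx[[ri]]) {
      pool <- setdiff(fmem, g)
      m <- min(design$ppi_interactors, length(pool))
      if (m > 0) {
        edges[[length(edges) + 1L]] <-
          cbind(genes[g], genes[sample(pool, m)])
      }
    }
  }
  nbg <- design$ppi_background_edges
  if (nbg > 0) {
    a <- sample.int(N, nbg, replace = TRUE)
    b <- sample.int(N, nbg, replace = TRUE)
    edges[[length(edges) + 1L]] <- cbind(genes[a], genes[b])
  }
  ppi <- interaction_graph(do.call(rbind, edges))

  signal <- which(vapply(design$regulons, function(r)
    r$delta != 0 && length(r$conditions) > 0, logical(1)))
  truth_triples <- do.call(rbind, lapply(signal, function(ri) {
    rg <- design$regulons[[ri]]
    data.frame(tf_label = tf_labels[rg$tfbs],
               tfbs_name = tfbs$info$name[rg$tfbs],
               func_name = funcs$info$name[rg$func],
               condition = conds[rg$conditions], stringsAsFactors = FALSE)
  })) %||% data.frame(tf_label = character(0), tfbs_name = character(0),
                      func_name = character(0), condition = character(0))
  truth_targets <- do.call(rbind, lapply(signal, function(ri) {
    rg <- design$regulons[[ri]]
    data.frame(tf_label = tf_labels[rg$tfbs],
               func_name = funcs$info$name[rg$func],
               gene = genes[ov_idx[[ri]]], stringsAsFactors = FALSE)
  })) %||% data.frame(tf_label = character(0), func_name = character(0),
                      gene = character(0))

  structure(
    list(tfbs = tfbs, funcs = funcs, fc = fc, ppi = ppi,
         truth = list(triples = truth_triples, targets = truth_targets,
                      design = design)),
    class = "regnet_simulation"
  )
}

#' Write a simulation to disk in the miner's input formats
#'
#' @param sim A `regnet_simulation`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "regnet_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("tfbs.gmt", "func.gmt", "fold_change.tsv",
                            "ppi.tsv", "ground_truth.json"))
  write_gmt(sim$tfbs, paths[1])
  write_gmt(sim$funcs, paths[2])
  write_fc_matrix(sim$fc, paths[3])
  write_interactions(sim$ppi, paths[4])
  jsonlite::write_json(
    list(triples = sim$truth$triples, targets = sim$truth$targets,
         tf_labels = stats::setNames(as.list(sim$tfbs$info$tf_label),
                                     sim$tfbs$info$name)),
    paths[5], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
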