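# Small in-code fixtures shared across test files.

# Write GMT lines to a temp file and return the path.
tmp_gmt <- function(lines) {
  path <- tempfile(fileext = ".gmt")
  writeLines(lines, path)
  path
}

# A one-condition fold-change fixture with a planted overlap shift:
# universe of `n_genes`, TFBS set = genes 1..set_size, functional set
# chosen so that the two sets share `overlap` genes; the overlap genes are
# shifted by `delta` (on top of N(0, sd) noise) and, optionally, the whole
# TFBS set is shifted by `parent_delta`.
screen_fixture <- function(n_genes = 1000, set_size = 500, overlap = 30,
                           delta = 2, parent_delta = 0, sd = 1, seed = 101) {
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  tf_idx <- seq_len(set_size)
  fn_idx <- seq(set_size - overlap + 1, 2 * set_size - overlap)
  tfbs <- gene_set_collection(list(T1 = genes[tf_idx]), category = "TFBS",
                              tf_label = "TF1")
  funcs <- gene_set_collection(list(F1 = genes[fn_idx]), category = "GO_BP")
  v <- stats::rnorm(n_genes, 0, sd)
  ov <- intersect(tf_idx, fn_idx)
  v[ov] <- v[ov] + delta
  v[tf_idx] <- v[tf_idx] + parent_delta
  fc <- matrix(v, ncol = 1, dimnames = list(genes, "C001"))
  list(tfbs = tfbs, funcs = funcs, fc = fc, overlap_genes = genes[ov])
}

# Hand-built mining inputs for network-assembly tests: one pair activated
# in `n_active` conditions out of `n_cond`.
assembly_fixture <- function(n_active = 10, n_cond = 15) {
  conds <- sprintf("C%03d", seq_len(n_cond))
  overlaps <- data.frame(
    tfbs_name = "T1", tf_label = "TF1", func_name = "F1",
    universe_size = 1000L, tfbs_size = 100L, func_size = 100L,
    overlap_size = 3L, p_value = 1e-6, q_value = 1e-5,
    stringsAsFactors = FALSE
  )
  overlaps$overlap_genes <- list(c("GA", "GB", "GC"))
  overlaps$pair_id <- "T1|F1"
  screened <- data.frame(
    pair_id = "T1|F1", tfbs_name = "T1", func_name = "F1",
    condition = conds, n_measured = 3L,
    z_overlap = 5, p_overlap = 1e-6, q_overlap = 1e-5,
    z_tfbs = 0.5, q_tfbs = 0.9, z_func = 0.4, q_func = 0.9,
    activated = c(rep(TRUE, n_active), rep(FALSE, n_cond - n_active)),
    stringsAsFactors = FALSE
  )
  list(overlaps = overlaps, screened = screened, conds = conds)
}
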