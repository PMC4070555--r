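test_that("association records require k supporting conditions (inclusive)", {
  fx <- assembly_fixture(n_active = 10)
  net <- assemble_network(fx$screened, fx$overlaps, k = 10)
  expect_equal(nrow(net$records), 1)
  expect_equal(net$records$n_conditions, 10)
  expect_equal(nrow(net$triples), 10)
  expect_setequal(net$triples$condition, fx$conds[1:10])

  fx9 <- assembly_fixture(n_active = 9)
  net9 <- assemble_network(fx9$screened, fx9$overlaps, k = 10)
  expect_equal(nrow(net9$records), 0)

  net1 <- assemble_network(fx9$screened, fx9$overlaps, k = 1)
  expect_equal(nrow(net1$triples), 9) # every activated pair-condition
  expect_error(assemble_network(fx$screened, fx$overlaps, k = 0))
})

test_that("record and triple counts never grow with k", {
  fx <- assembly_fixture(n_active = 12)
  prev_r <- Inf; prev_t <- Inf
  for (k in c(1, 5, 10, 13)) {
    net <- assemble_network(fx$screened, fx$overlaps, k = k)
    expect_lte(nrow(net$records), prev_r)
    expect_lte(nrow(net$triples), prev_t)
    expect_equal(sum(net$records$n_conditions), nrow(net$triples))
    prev_r <- nrow(net$records); prev_t <- nrow(net$triples)
  }
})

make_target_fixture <- function() {
  fx <- assembly_fixture(n_active = 12)
  net <- assemble_network(fx$screened, fx$overlaps, k = 10)
  sup <- net$records$supporting_conditions[[1]]
  fc <- matrix(0, 3, 15, dimnames = list(c("GA", "GB", "GD"), fx$conds))
  fc["GA", sup[1:3]] <- c(0.7, -0.8, 1.2)   # |log2FC| >= log2(1.5) in 3
  fc["GB", ] <- 0.2                          # never above the cutoff
  # GC absent from the matrix entirely
  list(net = net, fc = fc, sup = sup)
}

test_that("candidate targets obey the high fold-change rule", {
  fx <- make_target_fixture()
  tg <- select_candidate_targets(fx$net$records, fx$fc, k = 10, frac = 0.3)
  expect_setequal(tg$gene, c("GA", "GB", "GC")) # all overlap genes reported
  expect_true(all(tg$gene %in% fx$net$records$overlap_genes[[1]]))
  expect_equal(tg$n_highfc_conditions[tg$gene == "GA"], 3)
  expect_true(tg$passed[tg$gene == "GA"])      # 3 >= ceiling(0.3 * 10)
  expect_false(tg$passed[tg$gene == "GB"])     # all-zero-ish gene fails
  expect_false(tg$measured[tg$gene == "GC"])   # absent gene flagged
  expect_equal(tg$n_highfc_conditions[tg$gene == "GC"], 0)
  # strict reading needs count > 0.3 * k, i.e. 4
  st <- select_candidate_targets(fx$net$records, fx$fc, k = 10, strict = TRUE)
  expect_false(st$passed[st$gene == "GA"])
  # threshold 1.0 passes every measured overlap gene
  t1 <- select_candidate_targets(fx$net$records, fx$fc, fc_threshold = 1)
  expect_true(all(t1$passed[t1$measured]))
  expect_error(select_candidate_targets(fx$net$records, fx$fc,
                                        fc_threshold = 0.5))
})

test_that("raising the fold-change threshold never increases high-FC counts", {
  fx <- make_target_fixture()
  prev <- rep(Inf, 3)
  for (thr in c(1, 1.3, 1.5, 2, 4)) {
    tg <- select_candidate_targets(fx$net$records, fx$fc, fc_threshold = thr)
    cnt <- tg$n_highfc_conditions[order(tg$gene)]
    expect_true(all(cnt <= prev))
    prev <- cnt
  }
})

test_that("TF-level pooling unions passed targets across records", {
  records <- data.frame(
    pair_id = c("a|x", "b|y"), tfbs_name = c("a", "b"),
    tf_label = "TF9", func_name = c("x", "y"), stringsAsFactors = FALSE
  )
  targets <- data.frame(
    gene = c("A", "B", "B", "C", "D"),
    tf_label = "TF9",
    tfbs_name = c("a", "a", "b", "b", "b"),
    func_name = c("x", "x", "y", "y", "y"),
    n_highfc_conditions = c(3, 3, 4, 5, 0),
    measured = TRUE,
    passed = c(TRUE, TRUE, TRUE, TRUE, FALSE), stringsAsFactors = FALSE
  )
  expect_equal(pool_tf_targets(records, targets, "TF9"), c("A", "B", "C"))
  expect_warning(out <- pool_tf_targets(records, targets, "NOPE"), "NOPE")
  expect_equal(out, character(0))
})

test_that("per-record heat-map matrices line up genes and conditions", {
  fx <- make_target_fixture()
  hm <- record_heatmap_matrix(fx$net$records[1, ], fx$fc)
  expect_equal(dim(hm), c(3, 12))
  expect_equal(hm["GA", fx$sup[1]], 0.7)
  expect_true(all(is.na(hm["GC", ])))
})
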