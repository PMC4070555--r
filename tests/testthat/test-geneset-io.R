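test_that("GMT parsing collapses duplicates, upper-cases and validates", {
  p <- tmp_gmt("SETA\tdesc\tG1\tg2\tG2")
  gs <- read_gmt(p)
  expect_equal(length(gs), 1)
  expect_setequal(gs$sets$SETA, c("G1", "G2"))

  empty <- read_gmt(tmp_gmt(character(0)))
  expect_s3_class(empty, "gene_set_collection")
  expect_equal(length(empty), 0)

  expect_error(read_gmt(tmp_gmt(c("S1\td\tG1", "S1\td\tG2"))),
               "duplicate set name")
  expect_error(read_gmt(tmp_gmt(c("S1\td\tG1", "S2\tonly-two-fields"))),
               "line 2")
})

test_that("GMT round trip preserves set names and memberships", {
  gs <- gene_set_collection(
    list(A = c("TP53", "MDM2", "CDK1"), B = sprintf("G%02d", 1:15)),
    category = c("TFBS", "KEGG"), tf_label = c("TP53", NA),
    description = c("a", "b")
  )
  p <- tempfile(fileext = ".gmt")
  write_gmt(gs, p)
  back <- read_gmt(p)
  expect_equal(back$info$name, gs$info$name)
  expect_equal(back$sets, gs$sets)
  expect_equal(back$info$description, gs$info$description)
})

test_that("probe collapse averages per gene and ignores missing values", {
  m <- matrix(c(1, 3, 5, NA, 2, 4), nrow = 3, byrow = FALSE,
              dimnames = list(c("p1", "p2", "p3"), c("C1", "C2")))
  map <- data.frame(probe = c("p1", "p2", "p3"), gene = c("GA", "GA", "gb"))
  out <- collapse_probes(m, map)
  expect_equal(sort(rownames(out)), c("GA", "GB"))
  expect_equal(out["GA", "C1"], 2)       # mean(1, 3)
  expect_equal(out["GB", "C1"], 5)       # single probe passes through
  expect_equal(out["GA", "C2"], 2)       # mean(NA, 2) ignoring missing
  # unmapped probes are dropped; gene count = distinct mapped genes
  out2 <- collapse_probes(m, map[1:2, ])
  expect_equal(rownames(out2), "GA")
  # ambiguous probe -> error
  bad <- rbind(map, data.frame(probe = "p1", gene = "GC"))
  expect_error(collapse_probes(m, bad), "ambiguous")
})

test_that("size filter applies inclusive 10-500 bounds, optionally vs a universe", {
  sizes <- c(9, 10, 500, 501)
  sets <- lapply(sizes, function(s) sprintf("G%04d", seq_len(s)))
  names(sets) <- paste0("S", sizes)
  gs <- gene_set_collection(sets)
  kept <- filter_by_size(gs)
  expect_setequal(kept$info$name, c("S10", "S500"))
  expect_equal(length(filter_by_size(gs, 1, 1e6)), 4)  # identity bounds
  expect_equal(length(filter_by_size(gs["S10"][0])), 0) # empty collection
  expect_error(filter_by_size(gs, 0, 10))
  # measured against a universe lacking G0001: S10 drops to 9 measurable
  # genes (dropped) while S501 drops to 500 (now retained)
  uni <- sprintf("G%04d", 2:600)
  expect_setequal(filter_by_size(gs, universe = uni)$info$name,
                  c("S500", "S501"))
})

test_that("per-TF union sets pool all of a TF's TFBS sets", {
  sets <- list(
    AHR_01 = sprintf("A%02d", 1:12), AHR_02 = sprintf("A%02d", 5:20),
    AHR_03 = sprintf("B%02d", 1:10), AHR_Q5 = sprintf("C%02d", 1:11),
    OTHER_1 = sprintf("D%02d", 1:10)
  )
  gs <- gene_set_collection(sets, category = "TFBS",
                            tf_label = c(rep("AHR", 4), "OTH"))
  out <- build_tf_union_sets(gs)
  expect_equal(length(out), 6) # originals retained, one union added
  expect_true("AHR_all" %in% out$info$name)
  expect_setequal(out$sets$AHR_all,
                  unique(unlist(sets[1:4], use.names = FALSE)))
  # single-set TF gets no union; a TF-less collection is untouched
  expect_false("OTH_all" %in% out$info$name)
  solo <- gene_set_collection(sets[5], category = "TFBS", tf_label = "OTH")
  expect_equal(length(build_tf_union_sets(solo)), 1)
  # disjoint sets of sizes 10 and 20 -> union of 30
  dj <- gene_set_collection(
    list(X1 = sprintf("X%02d", 1:10), X2 = sprintf("Y%02d", 1:20)),
    category = "TFBS", tf_label = "XX"
  )
  expect_equal(length(build_tf_union_sets(dj)$sets$XX_all), 30)
})

test_that("union size is bounded by member sizes", {
  set.seed(5)
  for (r in 1:20) {
    sets <- lapply(1:3, function(i) sample(sprintf("G%03d", 1:100),
                                           sample(10:40, 1)))
    names(sets) <- paste0("S", 1:3)
    gs <- gene_set_collection(sets, category = "TFBS", tf_label = "TF")
    u <- build_tf_union_sets(gs)$sets$TF_all
    expect_lte(length(u), sum(lengths(sets)))
    expect_gte(length(u), max(vapply(gs$sets[1:3], length, integer(1))))
  }
})

test_that("fold-change matrix IO validates shape and round-trips", {
  m <- matrix(rnorm(12), 4, 3,
              dimnames = list(sprintf("g%d", 1:4), sprintf("C%d", 1:3)))
  p <- tempfile(fileext = ".tsv")
  write_fc_matrix(as_fc_matrix(m), p)
  back <- read_fc_matrix(p)
  expect_equal(back, as_fc_matrix(m), tolerance = 1e-12)
  expect_error(as_fc_matrix(matrix(1:4, 2)), "row names")
  dup <- m[c(1, 1, 2), ]
  expect_error(as_fc_matrix(dup), "unique")
  expect_silent(as_fc_matrix(dup, allow_duplicates = TRUE))
})
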