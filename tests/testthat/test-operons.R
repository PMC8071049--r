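test_that("gap rule merges across short insertions (fdxN pattern)", {
  ann <- toy_annotation(c("nifB", "x", "fdxN", "nifS", "nifU"))
  cl <- cluster_nif_loci(ann)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$members$nif_gene, c("nifB", "nifS", "nifU"))
  expect_equal(cl[[1]]$intervening_counts, c(2L, 0L))
})

test_that("four intervening genes split clusters (< 4 rule is strict)", {
  ann <- toy_annotation(c("nifB", "x", "x", "x", "x", "nifS", "nifU"))
  cl <- cluster_nif_loci(ann)
  expect_length(cl, 2)
  expect_equal(cl[[1]]$members$nif_gene, "nifB")
  expect_equal(cl[[2]]$members$nif_gene, c("nifS", "nifU"))
  # three intervening genes merge
  ann2 <- toy_annotation(c("nifB", "x", "x", "x", "nifS", "nifU"))
  expect_length(cluster_nif_loci(ann2), 1)
})

test_that("clusters never span contigs and clustering is idempotent", {
  ann <- toy_annotation_multi(list(c1 = c("nifH", "nifD"), c2 = c("nifK")))
  cl <- cluster_nif_loci(ann)
  expect_length(cl, 2)
  expect_equal(vapply(cl, function(x) x$contig_id, character(1)), c("c1", "c2"))
  expect_identical(cluster_ordinals(cluster_nif_loci(ann)),
                   cluster_ordinals(cl))
})

test_that("bridging rescues a singleton flanked by multi-gene clusters", {
  labs <- c("nifE", "nifN", rep("x", 5), "nifX", rep("x", 5), "nifW", "nifV")
  ann <- toy_annotation(labs)
  cl <- cluster_nif_loci(ann)
  expect_length(cl, 3)
  bridged <- bridge_orphans(cl, ann)
  expect_length(bridged, 1)
  m <- bridged[[1]]$members
  expect_true(m$bridged[m$nif_gene == "nifX"])
  expect_false(any(m$bridged[m$nif_gene != "nifX"]))
  # switch off: output identical to input
  expect_identical(
    cluster_ordinals(bridge_orphans(cl, ann, nif_config(bridging_enabled = FALSE))),
    cluster_ordinals(cl))
})

test_that("bridging requires multi-gene clusters on BOTH sides", {
  labs <- c("nifE", "nifN", rep("x", 5), "nifX")
  ann <- toy_annotation(labs)
  cl <- cluster_nif_loci(ann)
  expect_identical(cluster_ordinals(bridge_orphans(cl, ann)),
                   cluster_ordinals(cl))
})

test_that("a super-operon splits into the canonical operon calls", {
  ann <- toy_annotation(c("nifB", "nifS", "nifU", "nifH", "nifD", "nifK",
                          "nifE", "nifN", "nifX", "nifW"))
  cl <- cluster_nif_loci(ann)
  expect_length(cl, 1)
  calls <- split_and_match(cl[[1]])
  expect_setequal(vapply(calls, function(x) x$template, character(1)),
                  c("nifBSU", "nifHDK", "nifENXW"))
  expect_true(all(vapply(calls, function(x) x$status, character(1)) == "complete"))
})

test_that("partial operons report their missing members", {
  ann <- toy_annotation(c("nifV", "nifZ"))
  calls <- split_and_match(cluster_nif_loci(ann)[[1]])
  expect_length(calls, 1)
  expect_equal(calls[[1]]$template, "nifVZT")
  expect_equal(calls[[1]]$status, "partial")
  expect_equal(calls[[1]]$missing, "nifT")
})

test_that("nifK adjacent to nifENXW is cross-referenced, not a nifHDK call", {
  ann <- toy_annotation(c("nifK", "nifE", "nifN", "nifX", "nifW"))
  calls <- split_and_match(cluster_nif_loci(ann)[[1]])
  expect_length(calls, 1)
  expect_equal(calls[[1]]$template, "nifENXW")
  expect_true(calls[[1]]$nifk_crossref)
  expect_true("nifK" %in% calls[[1]]$extras)
})

test_that("insertions are counted and a label-free cluster warns", {
  ann <- toy_annotation(c("nifH", "x", "nifD", "x", "x", "nifK"))
  calls <- split_and_match(cluster_nif_loci(ann)[[1]])
  expect_equal(calls[[1]]$insertions, 3L)
  ann2 <- toy_annotation(c("x", "y"))
  ann2$nif_gene <- c("nifQ", NA)   # not a catalog label
  cl <- list(structure(list(genome_id = "G1", contig_id = "c1",
                            members = ann2[1, ], span = c(0L, 0L),
                            intervening_counts = integer(0)),
                       class = "nif_cluster"))
  expect_warning(res <- split_and_match(cl[[1]]), "no template")
  expect_length(res, 0)
})

test_that("dual operon sets are detected and partitioned by position", {
  labs <- c("nifH", "nifD", "nifK", rep("x", 60), "nifH", "nifD", "nifK")
  ann <- toy_annotation(labs)
  calls <- unlist(lapply(cluster_nif_loci(ann), split_and_match),
                  recursive = FALSE)
  res <- detect_dual_operon_sets(calls)
  expect_true(attr(res, "dual_set"))
  expect_setequal(vapply(res, function(x) x$set_label, character(1)),
                  c("set1", "set2"))
  lo <- vapply(res, function(x) min(x$members$ordinal), numeric(1))
  expect_true(lo[vapply(res, function(x) x$set_label, character(1)) == "set1"] <
                lo[vapply(res, function(x) x$set_label, character(1)) == "set2"])
  # different contigs count as distant
  ann2 <- toy_annotation_multi(list(c1 = c("nifH", "nifD", "nifK"),
                                    c2 = c("nifH", "nifD", "nifK")))
  calls2 <- unlist(lapply(cluster_nif_loci(ann2), split_and_match),
                   recursive = FALSE)
  expect_true(attr(detect_dual_operon_sets(calls2), "dual_set"))
})

test_that("single-copy genomes get set1 only and split fragments are marked", {
  ann <- toy_annotation(c("nifH", "nifD", "nifK", rep("x", 10),
                          "nifB", "nifS", "nifU"))
  calls <- unlist(lapply(cluster_nif_loci(ann), split_and_match),
                  recursive = FALSE)
  res <- detect_dual_operon_sets(calls)
  expect_false(attr(res, "dual_set"))
  expect_true(all(vapply(res, function(x) x$set_label, character(1)) == "set1"))
  # same-template fragments co-located -> split
  ann2 <- toy_annotation(c("nifB", rep("x", 6), "nifS", "nifU"))
  calls2 <- unlist(lapply(cluster_nif_loci(ann2), split_and_match),
                   recursive = FALSE)
  res2 <- detect_dual_operon_sets(calls2)
  expect_false(attr(res2, "dual_set"))
  expect_true(all(vapply(res2, function(x) x$status, character(1)) == "split"))
})

test_that("clustering equals the brute-force oracle on random tables", {
  set.seed(7)
  cfg <- nif_config()
  for (i in 1:80) {
    ann <- random_nif_table(max_genes = 30, n_contigs = sample(1:2, 1))
    got <- cluster_ordinals(bridge_orphans(cluster_nif_loci(ann, cfg), ann, cfg))
    expect_identical(got, oracle_clusters(ann, cfg))
  }
})

test_that("increasing max_gap never increases the number of clusters", {
  set.seed(21)
  for (i in 1:30) {
    ann <- random_nif_table(max_genes = 30)
    n_prev <- Inf
    for (gap in c(1, 2, 4, 8)) {
      n <- length(cluster_nif_loci(ann, nif_config(max_gap = gap)))
      expect_lte(n, n_prev)
      n_prev <- n
    }
  }
})

test_that("every nif gene appears in exactly one cluster", {
  set.seed(33)
  for (i in 1:20) {
    ann <- random_nif_table(max_genes = 30, n_contigs = 2)
    cl <- bridge_orphans(cluster_nif_loci(ann), ann)
    tags <- unlist(lapply(cl, function(x) x$members$locus_tag))
    expect_false(any(duplicated(tags)))
    expect_setequal(tags, ann$locus_tag[!is.na(ann$nif_gene)])
  }
})

test_that("respect_strand splits clusters at strand switches", {
  ann <- toy_annotation(c("nifH", "nifD", "nifK"))
  ann$strand <- c("+", "+", "-")
  expect_length(cluster_nif_loci(ann, nif_config(respect_strand = TRUE)), 2)
  expect_length(cluster_nif_loci(ann), 1)
})
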