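test_that("Yule trees have the right shape and are seed-deterministic", {
  tr <- simulate_species_tree(4, 1, seed = 42)
  expect_equal(length(tr$tip.label), 4)
  expect_equal(tr$Nnode, 3)
  expect_true(all(tr$edge.length > 0))
  expect_true(ape::is.rooted(tr))
  expect_identical(ape::write.tree(simulate_species_tree(9, 2, seed = 9)),
                   ape::write.tree(simulate_species_tree(9, 2, seed = 9)))
  expect_error(simulate_species_tree(3), ">= 4")
})

test_that("the root split matches the Yule expectation", {
  # under a Yule process the size of one root subtree is uniform on 1..n-1;
  # for n = 10 the expected smaller-child size is mean(pmin(1:9, 9:1))
  n <- 10
  expected <- mean(pmin(1:(n - 1), (n - 1):1))
  set.seed(99)
  sizes <- replicate(1000, {
    tr <- simulate_species_tree(n, 1)
    root <- n + 1L
    kids <- tr$edge[tr$edge[, 1] == root, 2]
    k <- min(vapply(kids, function(x) {
      if (x <= n) 1L else length(phangorn::Descendants(tr, x, "tips")[[1]])
    }, integer(1)))
    k
  })
  se <- stats::sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - expected), 3 * se + 1e-9)
})

test_that("sequence simulation: no-change limit, determinism, alphabet", {
  tr <- simulate_species_tree(6, 1, seed = 8)
  a0 <- simulate_sequences(tr, 40, rate = 0, seed = 1)
  expect_equal(length(unique(unname(a0))), 1)
  a1 <- simulate_sequences(tr, 40, rate = 0.5, seed = 2)
  a2 <- simulate_sequences(tr, 40, rate = 0.5, seed = 2)
  expect_identical(a1, a2)
  expect_false(identical(a0, a1))
  expect_true(all(strsplit(paste(a1, collapse = ""), "")[[1]] %in%
                    nifloss:::AA_ALPHABET))
})

test_that("pairwise p-distance matches the model's closed form", {
  # two leaves at a known path length; 50 replicates vs the exact expectation
  tr <- ape::read.tree(text = "((A:0.4,B:0.6):0.1,(C:0.3,D:0.2):0.15);")
  rate <- 0.5
  expected <- expected_p_distance(c(0.4, 0.6), rate)
  set.seed(5)
  L <- 300
  ps <- replicate(50, {
    aln <- simulate_sequences(tr, L, rate)
    protein_distance(aln[c("A", "B")], model = "p")["A", "B"]
  })
  se <- stats::sd(ps) / sqrt(length(ps))
  expect_lt(abs(mean(ps) - expected), 3 * se)
})

test_that("loss histories: boundaries and exact recursion calibration", {
  tr <- simulate_species_tree(20, 1, seed = 7)
  sc0 <- nif_scenario(seed = 1, loss_prob_per_edge = 0)
  set.seed(1)
  t0 <- simulate_histories(tr, sc0)
  expect_true(all(t0$diazotroph))
  expect_equal(length(t0$loss_edges_raw), 0)
  sc1 <- nif_scenario(seed = 1, loss_prob_per_edge = 1)
  set.seed(1)
  t1 <- simulate_histories(tr, sc1)
  expect_false(any(t1$diazotroph))
  # exact recursion: P(leaf non-diazotroph) = 1 - (1-p)^depth(leaf in edges)
  p <- 0.05
  depth <- nifloss:::.node_depths(tr)[seq_along(tr$tip.label)]
  expected_frac <- mean(1 - (1 - p)^depth)
  sc <- nif_scenario(seed = 1, loss_prob_per_edge = p)
  set.seed(525)
  fr <- replicate(500, mean(!simulate_histories(tr, sc)$diazotroph))
  se <- stats::sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - expected_frac), 3 * se)
})

test_that("scenarios are bit-identical under the same seed", {
  sc <- nif_scenario(seed = 17, n_taxa = 8, n_markers = 3, n_filler = 40,
                     n_random_hgt = 1)
  d1 <- simulate_scenario(sc)
  d2 <- simulate_scenario(sc)
  expect_identical(ape::write.tree(d1$species_tree),
                   ape::write.tree(d2$species_tree))
  expect_identical(d1$annotations, d2$annotations)
  expect_identical(d1$proteomes, d2$proteomes)
  expect_identical(d1$gene_alignments, d2$gene_alignments)
})

test_that("forced fusion puts a single fused nifEN record in every diazotroph", {
  sc <- nif_scenario(seed = 23, n_taxa = 6, n_markers = 2, n_filler = 40,
                     fusion_prob = 1, dual_set_prob = 0, loss_prob_per_edge = 0)
  ds <- simulate_scenario(sc)
  for (g in names(ds$annotations)) {
    ann <- ds$annotations[[g]]
    expect_equal(sum(ann$gene_label == "nifEN", na.rm = TRUE), 1)
    expect_equal(sum(ann$gene_label %in% c("nifE", "nifN")), 0)
    # the fused protein is the concatenation of the two component sequences
    tag <- ann$locus_tag[!is.na(ann$gene_label) & ann$gene_label == "nifEN"]
    expect_equal(nchar(ds$proteomes[[g]][[tag]]),
                 nchar(ds$gene_alignments$nifE[[g]]) +
                   nchar(ds$gene_alignments$nifN[[g]]))
  }
})

test_that("emitted datasets round-trip through the package readers", {
  sc <- nif_scenario(seed = 29, n_taxa = 6, n_markers = 3, n_filler = 40,
                     dual_set_prob = 0)
  ds <- simulate_scenario(sc)
  dir <- withr::local_tempdir()
  emit_dataset(ds, dir)
  back <- read_dataset(dir)
  # gene tables parse with zero records dropped
  for (g in names(ds$annotations)) {
    expect_equal(as.data.frame(back$annotations[[g]]),
                 as.data.frame(ds$annotations[[g]]))
  }
  # orthogroup table read back equals the truth
  key <- function(x) sort(paste(x$orthogroup_id, x$genome_id, x$protein_id))
  expect_equal(key(back$orthogroups), key(ds$orthogroups))
  expect_identical(lapply(back$proteomes, sort), lapply(ds$proteomes, sort))
  expect_equal(robinson_foulds(back$species_tree, ds$species_tree), 0)
  # emission is byte-deterministic
  dir2 <- withr::local_tempdir()
  emit_dataset(simulate_scenario(sc), dir2)
  f1 <- sort(list.files(dir, recursive = TRUE))
  expect_identical(f1, sort(list.files(dir2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
})

test_that("a clean scenario's operon calls equal the true layout", {
  sc <- nif_scenario(seed = 43, n_taxa = 8, n_markers = 2, n_filler = 60,
                     loss_prob_per_edge = 0, dual_set_prob = 0,
                     fusion_prob = 0)
  ds <- simulate_scenario(sc)
  catalog <- map_nif_orthogroups(ds$annotations, ds$orthogroups)
  for (g in names(ds$annotations)) {
    tagged <- tag_nif_candidates(ds$annotations[[g]], ds$orthogroups, catalog)
    calls <- call_operons(tagged, catalog = catalog)
    truth_blocks <- ds$layout[[g]]
    expect_equal(length(calls), length(truth_blocks))
    got <- sort(vapply(calls, function(cl)
      paste(sort(cl$members$ordinal), collapse = ","), character(1)))
    want <- sort(vapply(truth_blocks, function(b)
      paste(sort(b$ordinals), collapse = ","), character(1)))
    expect_equal(got, want)
    expect_true(all(vapply(calls, function(cl) cl$status, character(1)) ==
                      "complete"))
  }
})

test_that("extra HGT events target carriers and are logged", {
  sc <- nif_scenario(seed = 47, n_taxa = 10, n_markers = 2, n_filler = 40,
                     loss_prob_per_edge = 0.1, n_random_hgt = 1)
  ds <- simulate_scenario(sc)
  for (ev in ds$truth$hgt) {
    gt <- ds$gene_trees_true[[ev$gene]]
    expect_true(ev$target %in% gt$tip.label)
    # the transferred tip hangs off the root on a long branch
    nt <- length(gt$tip.label)
    pend <- gt$edge.length[gt$edge[, 2] == match(ev$target, gt$tip.label)]
    others <- gt$edge.length[gt$edge[, 2] <= nt &
                               gt$edge[, 2] != match(ev$target, gt$tip.label)]
    expect_gt(pend, 2 * mean(others))
  }
  # an explicit event targeting a lost lineage without a residual errors
  sc2 <- nif_scenario(seed = 48, n_taxa = 6, loss_prob_per_edge = 1,
                      residual_retention_prob = 0,
                      extra_hgt = list(list(target = "T001", gene = "nifS",
                                            multiplier = 5)))
  expect_error(simulate_scenario(sc2), "lost the repertoire")
})
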