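test_that("Dollo reconstruction: trivial and forced cases", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  h0 <- dollo_reconstruct(tr, c("A", "B", "C", "D"))
  expect_equal(h0$n_losses, 0)
  expect_setequal(h0$gain_clade, c("A", "B", "C", "D"))
  h2 <- dollo_reconstruct(tr, c("A", "C"))
  expect_equal(h2$n_losses, 2)
  expect_setequal(unlist(h2$loss_edges), c("B", "D"))
  expect_equal(oracle_dollo_min(tr, c("A", "C")), 2L)
  # gain defaults to the MRCA of the present taxa
  h1 <- dollo_reconstruct(tr, c("A", "B"))
  expect_setequal(h1$gain_clade, c("A", "B"))
  expect_equal(h1$n_losses, 0)
  # pinned gain must cover all present taxa
  expect_error(dollo_reconstruct(tr, c("A", "C"),
                                 gain_node = ape::getMRCA(tr, c("A", "B"))),
               "contradicts")
  expect_error(dollo_reconstruct(tr, character()), "empty")
  expect_error(dollo_reconstruct(tr, "Z"), "absent")
})

test_that("Dollo loss counts equal the brute-force minimum", {
  set.seed(37)
  for (i in 1:60) {
    tr <- random_resolved_tree(sample(4:10, 1))
    k <- sample(seq_len(length(tr$tip.label) - 1), 1)
    present <- sample(tr$tip.label, k)
    h <- dollo_reconstruct(tr, present)
    expect_equal(h$n_losses, oracle_dollo_min(tr, present))
    # loss clades partition the absent leaves under the gain
    lost <- as.character(unlist(h$loss_edges))
    expect_false(any(duplicated(lost)))
    expect_setequal(lost, as.character(setdiff(h$gain_clade, present)))
  }
})

test_that("adding a present taxon removes at most one loss event", {
  # monotone repair: making one absent leaf present can cancel at most the
  # single loss event that covered it (possibly splitting it into new ones)
  set.seed(41)
  for (i in 1:30) {
    tr <- random_resolved_tree(8)
    present <- sample(tr$tip.label, sample(2:6, 1))
    h <- dollo_reconstruct(tr, present)
    extra <- setdiff(tr$tip.label, present)
    if (!length(extra)) next
    h2 <- dollo_reconstruct(tr, c(present, sample(extra, 1)))
    expect_gte(h2$n_losses, h$n_losses - 1)
  }
})

test_that("no-loss alternative counts the gains a loss-free model needs", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(dollo_reconstruct(tr, c("A", "C"))$n_gains_no_loss, 2)
  expect_equal(dollo_reconstruct(tr, c("A", "B", "C", "D"))$n_gains_no_loss, 1)
  expect_equal(dollo_reconstruct(tr, c("A", "B", "C"))$n_gains_no_loss, 2)
})

test_that("a vertical family classifies as vertical from the true gene tree", {
  # gene tree identical to the species tree, no anomalous branch lengths
  sp <- ape::read.tree(text = paste0(
    "(((A:0.10,B:0.12):0.09,(C:0.11,D:0.10):0.12):0.08,",
    "((E:0.13,F:0.09):0.10,(G:0.11,H:0.12):0.09):0.11);"))
  for (tax in sp$tip.label) {
    call <- classify_gene_history(tax, "nifB", sp, sp)
    expect_equal(call$verdict, "vertical")
  }
})

test_that("a long root-proximal branch classifies as extra-phylum transfer", {
  # hand-built gene tree: X hangs off the root on a 5x branch
  gene <- ape::read.tree(
    text = "(X:2.5,((A:0.1,B:0.12):0.1,(C:0.09,D:0.11):0.14):0.1);")
  sp <- ape::read.tree(
    text = "(((A:0.1,X:0.1):0.05,B:0.12):0.1,(C:0.09,D:0.11):0.1);")
  call <- classify_gene_history("X", "nifS", gene, sp)
  expect_equal(call$verdict, "extra_phylum_hgt")
  expect_true(call$evidence$root_proximal)
  # the same branch attached deep in the tree is not extra-phylum
  gene2 <- ape::read.tree(
    text = "(((A:0.1,X:2.5):0.1,B:0.12):0.1,(C:0.09,D:0.11):0.14);")
  call2 <- classify_gene_history("X", "nifS", gene2, sp)
  expect_true(call2$verdict %in% c("unresolved", "vertical"))
  expect_error(classify_gene_history("Z", "nifS", gene, sp), "absent")
})

test_that("an incongruent placement without a long branch is intra-phylum", {
  sp <- ape::read.tree(
    text = "(((A:0.1,B:0.1):0.1,(C:0.1,X:0.1):0.1):0.1,((D:0.1,E:0.1):0.1,(F:0.1,G:0.1):0.1):0.1);")
  # X placed with F/G in the gene tree instead of with C
  gene <- ape::read.tree(
    text = "(((A:0.1,B:0.1):0.1,C:0.12):0.1,((D:0.1,E:0.1):0.1,((F:0.1,X:0.1):0.08,G:0.11):0.1):0.1);")
  call <- classify_gene_history("X", "nifB", gene, sp)
  expect_equal(call$verdict, "intra_phylum_hgt")
  expect_gte(call$evidence$rf_improvement, 2)
  # a congruent taxon in the same tree stays vertical
  call2 <- classify_gene_history("A", "nifB", gene, sp)
  expect_equal(call2$verdict, "vertical")
})

test_that("verdicts are stable under taxon relabelling", {
  sp <- ape::read.tree(
    text = "(((A:0.1,B:0.1):0.1,(C:0.1,X:0.1):0.1):0.1,((D:0.1,E:0.1):0.1,(F:0.1,G:0.1):0.1):0.1);")
  gene <- ape::read.tree(
    text = "(((A:0.1,B:0.1):0.1,C:0.12):0.1,((D:0.1,E:0.1):0.1,((F:0.1,X:0.1):0.08,G:0.11):0.1):0.1);")
  v1 <- classify_gene_history("X", "nifB", gene, sp)$verdict
  perm <- c(A = "q1", B = "q2", C = "q3", D = "q4", E = "q5", F = "q6",
            G = "q7", X = "q8")
  sp2 <- sp; sp2$tip.label <- unname(perm[sp$tip.label])
  gene2 <- gene; gene2$tip.label <- unname(perm[gene$tip.label])
  expect_equal(classify_gene_history("q8", "nifB", gene2, sp2)$verdict, v1)
})

test_that("summarize_history assembles the headline verdict", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  hist <- list(diazotroph = dollo_reconstruct(tr, c("A", "B", "C")))
  calls <- list(
    structure(list(taxon = "D", gene_name = "nifS",
                   verdict = "extra_phylum_hgt", evidence = list()),
              class = "gene_history_call"),
    structure(list(taxon = "A", gene_name = "nifB", verdict = "vertical",
                   evidence = list()), class = "gene_history_call"))
  rep <- summarize_history(calls, hist,
                           diazotroph = c(A = TRUE, B = TRUE, C = TRUE,
                                          D = FALSE),
                           carriers = data.frame(genome_id = "D",
                                                 gene = "nifS"))
  expect_match(rep$headline, "1 independent losses")
  expect_equal(rep$n_extra_phylum, 1)
  txt <- format(rep)
  expect_true(any(grepl("nifS D: extra_phylum_hgt", txt)))
  expect_true(any(grepl("diazotrophs: 3 / 4", txt)))
  # deterministic rendering
  expect_identical(txt, format(rep))
})

test_that("simulated no-HGT scenarios report gain, losses and zero transfers", {
  sc <- nif_scenario(seed = 4301, n_taxa = 12, n_markers = 3, n_filler = 60,
                     dual_set_prob = 0, fusion_prob = 0,
                     loss_prob_per_edge = 0.08)
  ds <- simulate_scenario(sc)
  res <- run_nif_pipeline(ds, species_tree = ds$ingroup_tree)
  h <- res$histories$diazotroph
  expect_setequal(h$gain_clade, ds$truth$canonical_gain)
  expect_equal(h$n_losses, ds$truth$n_canonical_losses)
  # extra-phylum false calls stay within the method's designed tolerance
  n_extra <- sum(res$report$hgt_calls$verdict == "extra_phylum_hgt")
  expect_lte(n_extra / nrow(res$report$hgt_calls), 0.05)
  # diazotroph verdicts match the simulated truth
  expect_equal(res$diazotroph[names(ds$truth$diazotroph)],
               ds$truth$diazotroph)
})
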