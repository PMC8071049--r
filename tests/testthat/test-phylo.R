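test_that("concatenation tiles markers and round-trips", {
  m1 <- c(tA = "MKVLAWGHER", tB = "MKVLAWGHDR")
  m2 <- c(tA = "CCCNNNQQQIIIFFF", tB = "CCCNNNQQQIIIFFW")
  cc <- concatenate_alignments(list(m1 = m1, m2 = m2))
  expect_equal(unique(nchar(cc)), 25L)
  expect_equal(attr(cc, "partitions")$start, c(1L, 11L))
  expect_equal(attr(cc, "partitions")$end, c(10L, 25L))
  back <- split_alignment(cc)
  expect_equal(back$m1, m1)
  expect_equal(back$m2, m2)
  # single marker: identity
  one <- concatenate_alignments(list(m1 = m1))
  expect_equal(as.character(one), unname(m1))
  # missing taxon errors unless fill_missing
  expect_error(concatenate_alignments(list(m1 = m1, m3 = c(tA = "AAAA"))),
               "tB")
  filled <- concatenate_alignments(list(m1 = m1, m3 = c(tA = "AAAA")),
                                   fill_missing = TRUE)
  expect_equal(substr(filled[["tB"]], 11, 14), "----")
  expect_error(concatenate_alignments(list(m = m1, m = m2)), "duplicate")
})

test_that("protein distances: identity, direct count, Poisson closed form", {
  aln <- c(x = "AAAAAAAAAA", y = "AAAAAAAAAA", z = "WWWWWAAAAA")
  D <- protein_distance(aln, model = "p")
  expect_equal(D["x", "y"], 0)
  expect_equal(D["x", "z"], 0.5)
  Dp <- protein_distance(aln, model = "poisson")
  expect_equal(Dp["x", "z"], -log(0.5), tolerance = 1e-12)
  # gap columns are ignored pairwise
  alng <- c(x = "AA--AAAAAA", y = "AAWWAAAAAA")
  expect_equal(protein_distance(alng, model = "p")["x", "y"], 0)
  # saturated pair hits the ceiling and is flagged
  alns <- c(x = "AAAA", y = "WWWW", z = "AAAW")
  Ds <- protein_distance(alns)
  expect_equal(Ds["x", "y"], 10)
  expect_true(attr(Ds, "saturated")["x", "y"])
  expect_error(protein_distance(c(x = "A---", y = "-WWW")), "comparable")
})

test_that("NJ recovers the worked quartet with exact edge lengths", {
  D <- matrix(c(0, 2, 3, 3,
                2, 0, 3, 3,
                3, 3, 0, 2,
                3, 3, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(D)
  expect_true(.split_ab_cd(tr))
  # all pendant edges 1, internal edge 1
  nt <- length(tr$tip.label)
  pend <- tr$edge.length[tr$edge[, 2] <= nt]
  expect_equal(sort(pend), rep(1, 4), tolerance = 1e-9)
  expect_equal(tr$edge.length[tr$edge[, 2] > nt], 1, tolerance = 1e-9)
  # recovered distances are additive
  expect_equal(unname(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]),
               unname(D), tolerance = 1e-9)
})

test_that("three taxa resolve by the three-point formulas", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  cop <- ape::cophenetic.phylo(tr)
  expect_equal(unname(cop[rownames(D), colnames(D)]), unname(D),
               tolerance = 1e-9)
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
  D2 <- D; D2[1, 2] <- 99
  expect_error(neighbor_joining(D2), "symmetric")
})

test_that("NJ is exact on additive matrices from random trees", {
  set.seed(3)
  for (i in 1:25) {
    tr <- random_resolved_tree(sample(5:12, 1))
    D <- ape::cophenetic.phylo(tr)
    est <- neighbor_joining(D)
    expect_equal(robinson_foulds(est, tr), 0)
    # independent cross-check: ape's NJ agrees on topology
    expect_equal(robinson_foulds(est, ape::nj(D)), 0)
  }
})

test_that("negative branch estimates are clamped to zero and logged", {
  # d(b,c) > d(a,b) + d(a,c) forces a negative three-point estimate for a
  D <- matrix(c(0, 1, 1,
                1, 0, 3,
                1, 3, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  expect_true(all(tr$edge.length >= 0))
  expect_gt(attr(tr, "clamped_deficit"), 0)
})

test_that("bootstrap support: concordant signal, determinism, reorder invariance", {
  # every column supports AB|CD
  aln <- c(A = paste0(strrep("A", 10), strrep("C", 10)),
           B = paste0(strrep("A", 10), strrep("C", 10)),
           C = paste0(strrep("W", 10), strrep("Y", 10)),
           D = paste0(strrep("W", 10), strrep("Y", 10)))
  tr <- bootstrap_support(aln, n_reps = 100, seed = 5)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_equal(max(sup, na.rm = TRUE), 100)
  # determinism and invariance to taxon order
  tr2 <- bootstrap_support(aln[c(3, 1, 4, 2)], n_reps = 100, seed = 5)
  expect_identical(sort(tr$node.label), sort(tr2$node.label))
  expect_error(bootstrap_support(aln, n_reps = 0), "n_reps")
})

test_that("bootstrap support is near 50 for a 50/50 conflicting signal", {
  # half the columns support AB|CD, half AC|BD
  n <- 30
  aln <- c(A = paste0(strrep("A", n), strrep("A", n)),
           B = paste0(strrep("A", n), strrep("W", n)),
           C = paste0(strrep("W", n), strrep("A", n)),
           D = paste0(strrep("W", n), strrep("W", n)))
  tr <- bootstrap_support(aln, n_reps = 400, seed = 5)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  sup <- sup[!is.na(sup)]
  # binomial 99% bounds around 0.5 for 400 draws: ~ 0.5 +- 2.58*sqrt(.25/400)
  expect_true(all(sup >= 0 & sup <= 100))
  expect_lt(abs(max(sup) - 50), 14)
})

test_that("outgroup rooting splits the stem edge and validates the outgroup", {
  tr <- ape::read.tree(text = "((A:1,B:1):0.5,(C:1,D:1):0.5);")
  r1 <- root_at_outgroup(tr, "D")
  expect_true(ape::is.rooted(r1))
  expect_true(is_monophyletic(r1, c("A", "B", "C"))$monophyletic)
  r2 <- root_at_outgroup(tr, c("C", "D"))
  expect_true(is_monophyletic(r2, c("C", "D"))$monophyletic)
  # stem split evenly: both root edges equal
  root <- length(r2$tip.label) + 1L
  re <- r2$edge.length[r2$edge[, 1] == root]
  expect_equal(re[1], re[2])
  expect_error(root_at_outgroup(tr, c("A", "C")), "paraphyletic")
  expect_error(root_at_outgroup(tr, "Z"), "absent")
})

test_that("rooting then unrooting preserves the bipartition set", {
  set.seed(11)
  for (i in 1:30) {
    tr <- ape::unroot(random_resolved_tree(sample(5:10, 1)))
    og <- sample(tr$tip.label, 1)
    rooted <- root_at_outgroup(tr, og)
    expect_setequal(tree_splits(rooted), tree_splits(tr))
  }
})

test_that("Robinson-Foulds: identity, the 4-taxon resolutions, errors", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(robinson_foulds(t1, t1), 0)
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(robinson_foulds(t1, t2), 2)
  t3 <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(robinson_foulds(t1, t3), "differ")
})

test_that("Robinson-Foulds matches phangorn on random tree pairs", {
  set.seed(13)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    t1 <- random_resolved_tree(n)
    t2 <- random_resolved_tree(n)
    expect_equal(robinson_foulds(t1, t2),
                 as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2))))
  }
})

test_that("monophyly verdicts match the exhaustive clade oracle", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_true(is_monophyletic(tr, c("A", "B"))$monophyletic)
  v <- is_monophyletic(tr, c("A", "C"))
  expect_false(v$monophyletic)
  expect_setequal(v$intruders, c("B", "D"))
  expect_error(is_monophyletic(tr, c("A", "Z")), "absent")
  set.seed(17)
  for (i in 1:60) {
    t <- random_resolved_tree(sample(5:10, 1))
    grp <- sample(t$tip.label, sample(2:4, 1))
    got <- is_monophyletic(t, grp)
    want <- oracle_monophyly(t, grp)
    expect_equal(got$monophyletic, want$monophyletic)
    expect_equal(sort(got$intruders), want$intruders)
  }
})

test_that("branch-length outliers: zero spread warns, a 10x edge is flagged", {
  eq <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1,E:1);")
  expect_warning(out <- branch_length_outliers(eq), "equal")
  expect_false(any(out$flagged))
  # hand-computed: lengths {0.08,0.1,0.12,0.1,0.1,1.0}; median 0.1, raw MAD
  # 0.01 -> scaled 0.014826; z(1.0) = 0.9/0.014826
  tr <- ape::read.tree(
    text = "((A:0.08,B:0.1):0.12,(C:0.1,D:1.0):0.1);")
  out <- branch_length_outliers(tr, k = 3)
  flagged <- out[out$flagged, ]
  expect_equal(nrow(flagged), 1)
  expect_equal(flagged$tip, "D")
  expect_equal(flagged$z, 0.9 / (1.4826 * 0.01), tolerance = 1e-9)
  expect_error(branch_length_outliers(ape::read.tree(text = "(A:1,B:1,C:2);")),
               "at least 4")
})

test_that("root-proximal attachment is recognised", {
  # long branch hanging directly off the root vs deep in the tree
  tr <- ape::read.tree(
    text = "(X:5,((A:0.1,B:0.12):0.1,(C:0.09,D:0.11):0.13):0.1);")
  out <- branch_length_outliers(tr, k = 3)
  x <- out[!is.na(out$tip) & out$tip == "X", ]
  expect_true(x$flagged)
  expect_true(x$root_proximal)
})
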