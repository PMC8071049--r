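.quote_label <- function(x) {
  bad <- grepl("[(),:;'\\[\\]\\s]", x)
  x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
  x
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration with the Q criterion. Two determinism
#' guarantees beyond the textbook algorithm: ties in Q are broken by the
#' lexicographic order of the smallest taxon labels in the joined subtrees,
#' and negative branch-length estimates are clamped to zero (the total clamped
#' deficit is returned as attribute `clamped_deficit`). On an additive matrix
#' the generating tree is recovered exactly.
#'
#' @param D symmetric distance matrix with taxon dimnames (or a `dist`).
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  M <- as.matrix(D)
  if (is.null(rownames(M))) stop("distance matrix needs taxon dimnames")
  if (nrow(M) < 3) stop("need at least 3 taxa")
  if (max(abs(M - t(M))) > 1e-8) stop("distance matrix is not symmetric")
  labels <- rownames(M)
  nwk <- .quote_label(labels)
  key <- labels       # smallest original taxon label per active subtree
  deficit <- 0
  clamp <- function(l) {
    if (l < 0) { deficit <<- deficit - l; 0 } else l
  }
  n <- nrow(M)
  while (n > 3) {
    r <- rowSums(M)
    Q <- (n - 2) * M - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-10 * max(1, abs(qmin))
    cand <- which(Q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    k1 <- pmin(key[cand[, 1]], key[cand[, 2]])
    k2 <- pmax(key[cand[, 1]], key[cand[, 2]])
    pick <- order(k1, k2)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    li <- M[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- M[i, j] - li
    if (li < 0) { deficit <- deficit - li; lj <- M[i, j]; li <- 0 }
    if (lj < 0) { deficit <- deficit - lj; li <- M[i, j]; lj <- 0 }
    new_nwk <- sprintf("(%s:%.15g,%s:%.15g)", nwk[i], li, nwk[j], lj)
    du <- (M[i, ] + M[j, ] - M[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    M <- rbind(cbind(M[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    key <- c(key[keep], min(key[c(i, j)]))
    rownames(M) <- colnames(M) <- key
    n <- n - 1
  }
  la <- clamp((M[1, 2] + M[1, 3] - M[2, 3]) / 2)
  lb <- clamp((M[1, 2] + M[2, 3] - M[1, 3]) / 2)
  lc <- clamp((M[1, 3] + M[2, 3] - M[1, 2]) / 2)
  txt <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);", nwk[1], la, nwk[2], lb,
                 nwk[3], lc)
  tree <- ape::read.tree(text = txt)
  attr(tree, "clamped_deficit") <- deficit
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Columns of the alignment are resampled with replacement `n_reps` times; the
#' support of each internal edge of the full-data NJ tree is the percentage of
#' replicate trees containing the same bipartition. Supports are written as
#' internal node labels. Reproducible for a fixed seed and invariant to the
#' row order of the alignment.
#'
#' @param alignment named character vector of aligned sequences.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param model distance model, see [protein_distance()].
#' @param seed integer seed for the column resampling.
#' @return the full-data NJ `phylo` with integer `node.label` supports (root
#'   label empty).
#' @export
bootstrap_support <- function(alignment, n_reps = 100, model = "poisson",
                              seed = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  alignment <- alignment[order(names(alignment))]  # row-order invariance
  L <- .check_alignment(alignment)
  full <- neighbor_joining(protein_distance(alignment, model))
  full_splits <- tree_splits(full)
  counts <- stats::setNames(numeric(length(full_splits)), full_splits)
  M <- .alignment_matrix(alignment)
  set.seed(seed)
  for (rep in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    boot <- apply(M[, cols, drop = FALSE], 1, paste, collapse = "")
    names(boot) <- names(alignment)
    bt <- neighbor_joining(protein_distance(boot, model))
    hits <- full_splits %in% tree_splits(bt)
    counts[hits] <- counts[hits] + 1
  }
  support <- round(100 * counts / n_reps)
  # map supports onto internal nodes of the full tree
  nt <- length(full$tip.label)
  sets <- .node_tip_sets(full)
  labs <- character(full$Nnode)
  for (e in which(full$edge[, 2] > nt)) {
    child <- full$edge[e, 2]
    k <- .split_key(sets[[child]], sort(full$tip.label))
    if (!is.na(k) && k %in% names(support)) {
      labs[child - nt] <- as.character(support[[k]])
    }
  }
  full$node.label <- labs
  full
}
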