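# descendant tip labels for every node (tips + internals), as sorted character
.node_tip_sets <- function(tree) {
  nt <- length(tree$tip.label)
  sets <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) sets[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(sets, sort)
}

# canonical key of a bipartition given the full (sorted) taxon set: the side
# NOT containing the first taxon; NA for trivial splits
.split_key <- function(side, all_taxa) {
  if (all_taxa[1] %in% side) side <- setdiff(all_taxa, side)
  if (length(side) < 2 || length(side) > length(all_taxa) - 2) return(NA_character_)
  paste(side, collapse = "\r")
}

#' Non-trivial bipartitions of a tree
#'
#' @param tree a `phylo`.
#' @return character vector of canonical split keys (taxa of the side not
#'   containing the alphabetically first taxon, joined by `"\r"`), computed on
#'   the unrooted topology.
#' @export
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  nt <- length(tree$tip.label)
  all_taxa <- sort(tree$tip.label)
  sets <- .node_tip_sets(tree)
  keys <- vapply(which(tree$edge[, 2] > nt), function(e)
    .split_key(sets[[tree$edge[e, 2]]], all_taxa), character(1))
  unique(keys[!is.na(keys)])
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the two trees' sets of non-trivial
#' bipartitions, computed on the unrooted topologies. Zero iff the unrooted
#' topologies are identical.
#'
#' @param t1,t2 `phylo` trees on the same leaf set.
#' @return a non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    stop("leaf sets differ: only in t1 {",
         paste(setdiff(l1, l2), collapse = ", "), "}, only in t2 {",
         paste(setdiff(l2, l1), collapse = ", "), "}")
  }
  s1 <- tree_splits(t1); s2 <- tree_splits(t2)
  sum(!(s1 %in% s2)) + sum(!(s2 %in% s1))
}

# RF between the two trees after removing one taxon, computed by projecting
# precomputed split sets (equivalent to drop.tip + robinson_foulds)
.rf_project_drop <- function(splits1, splits2, all_taxa, drop) {
  taxa <- setdiff(all_taxa, drop)
  project <- function(keys) {
    out <- vapply(keys, function(k) {
      side <- setdiff(strsplit(k, "\r", fixed = TRUE)[[1]], drop)
      .split_key(side, taxa)
    }, character(1), USE.NAMES = FALSE)
    unique(out[!is.na(out)])
  }
  p1 <- project(splits1); p2 <- project(splits2)
  sum(!(p1 %in% p2)) + sum(!(p2 %in% p1))
}

#' Root a tree on the edge leading to an outgroup
#'
#' The root is placed on the edge separating the outgroup clade from the rest,
#' splitting that edge's length evenly across the new root.
#'
#' @param tree a `phylo` (rooted or unrooted).
#' @param outgroup_taxa character vector of outgroup tip labels.
#' @return a rooted `phylo`.
#' @export
root_at_outgroup <- function(tree, outgroup_taxa) {
  missing <- setdiff(outgroup_taxa, tree$tip.label)
  if (length(missing)) stop("outgroup taxa absent: ", paste(missing, collapse = ", "))
  all_taxa <- sort(tree$tip.label)
  if (length(outgroup_taxa) > 1 &&
      length(outgroup_taxa) < length(all_taxa) - 1) {
    k <- .split_key(sort(outgroup_taxa), all_taxa)
    if (!(k %in% tree_splits(tree))) stop("outgroup paraphyletic")
  }
  rooted <- ape::root(tree, outgroup = outgroup_taxa, resolve.root = TRUE)
  # split the stem length evenly across the two root edges
  root <- length(rooted$tip.label) + 1L
  re <- which(rooted$edge[, 1] == root)
  if (length(re) == 2) {
    total <- sum(rooted$edge.length[re])
    rooted$edge.length[re] <- total / 2
  }
  rooted
}

#' Test a taxon group for monophyly
#'
#' The group is monophyletic iff the smallest clade of the rooted tree
#' containing all its taxa contains no other taxa; otherwise the intruding
#' taxa are listed.
#'
#' @param tree a rooted `phylo`.
#' @param taxa character vector (the group).
#' @return list with `monophyletic` (logical), `clade_taxa` (tips of the
#'   smallest containing clade) and `intruders` (clade taxa not in the group).
#' @export
is_monophyletic <- function(tree, taxa) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing)) stop("group taxa absent from tree: ",
                            paste(missing, collapse = ", "))
  if (length(taxa) == 1) {
    return(list(monophyletic = TRUE, clade_taxa = taxa, intruders = character()))
  }
  node <- ape::getMRCA(tree, taxa)
  clade <- .node_tip_sets(tree)[[node]]
  intruders <- setdiff(clade, taxa)
  list(monophyletic = length(intruders) == 0, clade_taxa = clade,
       intruders = intruders)
}

# number of edges from the root to each node
.node_depths <- function(tree) {
  nt <- length(tree$tip.label)
  depth <- rep(NA_real_, nt + tree$Nnode)
  depth[nt + 1L] <- 0
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  for (e in seq_len(nrow(edges))) {
    depth[edges[e, 2]] <- depth[edges[e, 1]] + 1
  }
  depth
}

#' Flag branch-length outliers by robust z-score
#'
#' For each edge in scope, z = (length - median) / (1.4826 * MAD) over all
#' in-scope edge lengths; edges with z > k are flagged. The report notes
#' whether a flagged edge attaches root-proximally (the depth of its parent
#' node, in edges from the root, is below the median node depth of the tree).
#' When all in-scope lengths are equal (MAD = 0) nothing is flagged and a
#' warning is raised.
#'
#' @param tree a `phylo` with branch lengths (rooted trees give meaningful
#'   root-proximal calls; an unrooted tree is used as stored).
#' @param k flagging threshold on the robust z (default 3).
#' @param scope which edges enter the statistic: external (pendant), internal,
#'   or both.
#' @return data frame with one row per in-scope edge: parent, child, tip label
#'   (external edges), length, z, flagged, root_proximal.
#' @export
branch_length_outliers <- function(tree, k = 3, scope = c("both", "external", "internal")) {
  scope <- match.arg(scope)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  nt <- length(tree$tip.label)
  ext <- tree$edge[, 2] <= nt
  in_scope <- switch(scope, both = rep(TRUE, nrow(tree$edge)),
                     external = ext, internal = !ext)
  if (sum(in_scope) < 4) stop("need at least 4 edges in scope")
  len <- tree$edge.length[in_scope]
  med <- stats::median(len)
  s <- stats::mad(len)     # constant 1.4826
  z <- if (s > 0) (len - med) / s else rep(0, length(len))
  if (s == 0) warning("all in-scope edge lengths equal; no outliers flagged")
  depth <- .node_depths(tree)
  med_depth <- stats::median(depth, na.rm = TRUE)
  idx <- which(in_scope)
  out <- data.frame(
    parent = tree$edge[idx, 1], child = tree$edge[idx, 2],
    tip = ifelse(tree$edge[idx, 2] <= nt, tree$tip.label[tree$edge[idx, 2]],
                 NA_character_),
    length = len, z = z, flagged = z > k & s > 0,
    root_proximal = depth[tree$edge[idx, 1]] < med_depth,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
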