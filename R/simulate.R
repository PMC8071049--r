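#' Define a synthetic nif evolution scenario
#'
#' Bundles every parameter of the ground-truth generator. Defaults emulate the
#' structure of the cyanobacterial nif data: a 20-taxon Yule species tree, 31
#' concatenable marker proteins, thirteen nif genes with the observed mean
#' lengths of the short accessory proteins (nifX 137, nifW 106, nifZ 94,
#' nifT 67; 300 otherwise), whole-repertoire loss on ~5% of edges, rare
#' retention of a residual nifS/nifV in lost lineages, occasional fused nifEN,
#' occasional duplicated ("nif2-like") operon sets arriving by one
#' intra-phylum transfer, and optional extra-phylum transfers modelled as
#' long root-proximal attachments.
#'
#' @param seed integer; the same seed yields a bit-identical scenario.
#' @param n_taxa number of ingroup taxa (>= 4).
#' @param birth_rate Yule birth rate.
#' @param n_markers,marker_length species-tree marker proteins.
#' @param nif_lengths named integer vector of per-gene protein lengths.
#' @param substitution per-site replacement rate per unit branch length.
#' @param loss_prob_per_edge probability a lineage loses the whole nif
#'   repertoire on an edge.
#' @param residual_retention_prob probability a lost lineage keeps one of
#'   nifS/nifV.
#' @param insertion_prob probability of a filler-gene insertion at an
#'   operon-internal junction.
#' @param fusion_prob probability a diazotroph genome carries fused nifEN.
#' @param dual_set_prob probability the scenario contains a duplicated nif
#'   operon set transferred into one clade.
#' @param extra_hgt explicit list of extra-phylum transfer events, each
#'   `list(target =, gene =, multiplier =)`; `target`/`gene` may be `NA` to be
#'   drawn at simulation time.
#' @param n_random_hgt number of additional randomly targeted extra-phylum
#'   transfer events.
#' @param hgt_multiplier pendant-branch multiplier of transferred genes
#'   (relative to the gene tree's mean pendant length).
#' @param n_filler background (non-nif) genes per genome.
#' @param include_outgroup add an outgroup taxon ("Outgroup") to the species
#'   tree and markers, used for rooting the estimated tree.
#' @return list of class `nif_scenario`.
#' @export
nif_scenario <- function(seed = 1, n_taxa = 20, birth_rate = 1,
                         n_markers = 31, marker_length = 200,
                         nif_lengths = NULL, substitution = 0.3,
                         loss_prob_per_edge = 0.05,
                         residual_retention_prob = 0.05,
                         insertion_prob = 0.3, fusion_prob = 0.1,
                         dual_set_prob = 0.1, extra_hgt = list(),
                         n_random_hgt = 0, hgt_multiplier = 5,
                         n_filler = 150, include_outgroup = TRUE) {
  genes <- nif_catalog()$gene_names
  default_len <- stats::setNames(rep(300L, length(genes)), genes)
  default_len[c("nifX", "nifW", "nifZ", "nifT")] <- c(137L, 106L, 94L, 67L)
  if (!is.null(nif_lengths)) default_len[names(nif_lengths)] <- nif_lengths
  probs <- c(loss_prob_per_edge, residual_retention_prob, insertion_prob,
             fusion_prob, dual_set_prob)
  stopifnot(all(probs >= 0 & probs <= 1), all(default_len > 0),
            n_taxa >= 4, marker_length > 0, substitution >= 0)
  structure(list(seed = as.integer(seed), n_taxa = as.integer(n_taxa),
                 birth_rate = birth_rate, n_markers = as.integer(n_markers),
                 marker_length = as.integer(marker_length),
                 nif_lengths = default_len, substitution = substitution,
                 loss_prob_per_edge = loss_prob_per_edge,
                 residual_retention_prob = residual_retention_prob,
                 insertion_prob = insertion_prob, fusion_prob = fusion_prob,
                 dual_set_prob = dual_set_prob, extra_hgt = extra_hgt,
                 n_random_hgt = as.integer(n_random_hgt),
                 hgt_multiplier = hgt_multiplier,
                 n_filler = as.integer(n_filler),
                 include_outgroup = isTRUE(include_outgroup)),
            class = "nif_scenario")
}

#' @export
print.nif_scenario <- function(x, ...) {
  cat(sprintf("<nif_scenario> seed=%d, %d taxa, loss=%g/edge, dual=%g, fusion=%g, hgt events=%d\n",
              x$seed, x$n_taxa, x$loss_prob_per_edge, x$dual_set_prob,
              x$fusion_prob, length(x$extra_hgt) + x$n_random_hgt))
  invisible(x)
}

#' Simulate a Yule species tree
#'
#' Forward birth-only simulation: starting from the two root lineages, waiting
#' times are exponential with rate (number of lineages) x `birth_rate`, the
#' splitting lineage is chosen uniformly, and one final waiting time separates
#' the last split from the present so every pendant edge is positive. Leaves
#' are labelled T001..Tnnn.
#'
#' @param n_taxa number of leaves (>= 4).
#' @param birth_rate birth rate (> 0).
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return a rooted `phylo` with positive branch lengths.
#' @export
simulate_species_tree <- function(n_taxa, birth_rate = 1, seed = NULL) {
  if (n_taxa < 4) stop("n_taxa must be >= 4")
  if (!is.null(seed)) set.seed(seed)
  # node records: parent id, birth time; ids 1..k as created, id 0 = root
  parent <- c(0L, 0L)
  btime <- c(0, 0)
  active <- c(1L, 2L)
  now <- 0
  nid <- 2L
  while (length(active) < n_taxa) {
    now <- now + stats::rexp(1, length(active) * birth_rate)
    i <- active[sample.int(length(active), 1)]
    btime_i <- now
    parent <- c(parent, i, i)
    btime <- c(btime, btime_i, btime_i)
    active <- c(setdiff(active, i), nid + 1L, nid + 2L)
    nid <- nid + 2L
  }
  now <- now + stats::rexp(1, n_taxa * birth_rate)
  end_time <- rep(NA_real_, nid)
  for (x in seq_len(nid)) {
    kids <- which(parent == x)
    end_time[x] <- if (length(kids)) btime[kids[1]] else now
  }
  leaves <- sort(active)
  tip_label <- sprintf("T%03d", seq_along(leaves))
  ape_id <- integer(nid + 1L)          # +1 for root id 0
  ape_id[leaves + 1L] <- seq_along(leaves)
  internals <- c(0L, setdiff(seq_len(nid), leaves))
  internals <- internals[order(internals)]          # root (0) first
  ape_id[internals + 1L] <- length(leaves) + seq_along(internals)
  edge <- cbind(ape_id[parent + 1L], ape_id[seq_len(nid) + 1L])
  edge.length <- end_time - btime
  tree <- list(edge = edge, edge.length = edge.length, tip.label = tip_label,
               Nnode = length(internals))
  class(tree) <- "phylo"
  ape::reorder.phylo(tree, "cladewise")
}

#' Simulate protein sequences along a tree
#'
#' The root sequence is uniform over the 20-letter alphabet; along each edge
#' every site is replaced with probability 1 - exp(-rate x edge length), the
#' new state uniform over the other 19 letters. Gap-free by construction.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param length number of sites.
#' @param rate per-site replacement rate per unit branch length.
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return named character vector (one row per leaf).
#' @export
simulate_sequences <- function(tree, length, rate, seed = NULL) {
  stopifnot(length > 0, rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  nt <- base::length(tree$tip.label)
  root <- nt + 1L
  seqs <- vector("list", nt + tree$Nnode)
  seqs[[root]] <- sample.int(20L, length, replace = TRUE)
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    s <- seqs[[p]]
    pr <- 1 - exp(-rate * tr$edge.length[e])
    hit <- which(stats::runif(length) < pr)
    if (base::length(hit)) {
      s[hit] <- ((s[hit] - 1L + sample.int(19L, base::length(hit),
                                           replace = TRUE)) %% 20L) + 1L
    }
    seqs[[ch]] <- s
  }
  out <- vapply(seq_len(nt), function(i)
    paste(AA_ALPHABET[seqs[[i]]], collapse = ""), character(1))
  names(out) <- tree$tip.label
  out
}

#' Exact expected p-distance of the sequence simulator
#'
#' For two leaves joined by edges of lengths `edge_lengths`, the per-edge
#' replacement step (probability q = 1 - exp(-rate x l), new state uniform
#' over the other 19 letters) leaves the identity eigenvalue 1 - (20/19) q, so
#' the expected proportion of differing sites is
#' (19/20) (1 - prod(1 - (20/19) q_e)). For short edges this converges to the
#' continuous-chain form (19/20)(1 - exp(-(20/19) rate t)).
#'
#' @param edge_lengths lengths of the edges on the leaf-to-leaf path.
#' @param rate replacement rate used in [simulate_sequences()].
#' @return expected p-distance in \[0, 0.95\].
#' @export
expected_p_distance <- function(edge_lengths, rate) {
  q <- 1 - exp(-rate * edge_lengths)
  (19 / 20) * (1 - prod(1 - (20 / 19) * q))
}

# --- history simulation ------------------------------------------------------

#' Simulate gain/loss/transfer history of the nif repertoire on a tree
#'
#' The repertoire is gained at the root; on each edge a lineage carrying it
#' loses it with `loss_prob_per_edge` (losses are inherited). A lost leaf
#' lineage keeps one residual gene (nifS or nifV) with
#' `residual_retention_prob`. With probability `dual_set_prob` one clade of
#' diazotrophs receives a duplicated "set2" operon complement from a donor
#' lineage elsewhere in the tree. Extra-phylum transfer events replace the
#' evolutionary path of one gene in one carrier taxon with a long attachment
#' to the root region of that gene's tree (pendant = multiplier x mean pendant
#' length). Every event is logged. Also records the observable canonical form
#' of the loss history (gain = MRCA of surviving carriers; losses = maximal
#' absent clades), which is what any single-gain reconstruction can recover.
#'
#' @param tree rooted ingroup `phylo`.
#' @param scenario a [nif_scenario()]; the caller controls the RNG stream.
#' @return list of class `nif_ground_truth`.
#' @export
simulate_histories <- function(tree, scenario) {
  nt <- length(tree$tip.label)
  sets <- .node_tip_sets(tree)
  tr <- ape::reorder.phylo(tree, "cladewise")
  has <- rep(TRUE, nt + tree$Nnode)
  loss_edges <- list()
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    if (!has[p]) { has[ch] <- FALSE; next }
    if (stats::runif(1) < scenario$loss_prob_per_edge) {
      has[ch] <- FALSE
      loss_edges[[length(loss_edges) + 1L]] <- sets[[ch]]
    }
  }
  diazotroph <- stats::setNames(has[seq_len(nt)], tree$tip.label)
  residuals <- character(0)
  for (tax in names(diazotroph)[!diazotroph]) {
    if (stats::runif(1) < scenario$residual_retention_prob) {
      residuals[tax] <- sample(c("nifS", "nifV"), 1)
    }
  }
  # dual operon set: one intra-phylum transfer into a clade of diazotrophs
  dual <- NULL
  if (stats::runif(1) < scenario$dual_set_prob) {
    cand <- which(seq_along(sets) > nt & seq_along(sets) != nt + 1L)
    cand <- cand[vapply(cand, function(x)
      all(diazotroph[sets[[x]]]) && length(sets[[x]]) >= 2 &&
        length(sets[[x]]) <= nt / 2, logical(1))]
    if (length(cand)) {
      recipient <- cand[sample.int(length(cand), 1)]
      donors <- names(diazotroph)[diazotroph &
                                    !(names(diazotroph) %in% sets[[recipient]])]
      if (length(donors)) {
        donor <- donors[sample.int(length(donors), 1)]
        dual <- list(recipient_node = recipient,
                     recipient_leaves = sets[[recipient]],
                     donor = donor,
                     reference_genome = sort(sets[[recipient]])[1])
      }
    }
  }
  # extra-phylum transfers: targets must already carry the gene
  events <- scenario$extra_hgt
  if (scenario$n_random_hgt > 0) {
    events <- c(events, replicate(scenario$n_random_hgt,
                                  list(target = NA, gene = NA,
                                       multiplier = scenario$hgt_multiplier),
                                  simplify = FALSE))
  }
  hgt <- list()
  for (ev in events) {
    gene <- ev$gene
    if (is.na(gene) || is.null(gene)) gene <- sample(names(scenario$nif_lengths), 1)
    carriers <- c(names(diazotroph)[diazotroph],
                  names(residuals)[residuals == gene])
    target <- ev$target
    if (is.na(target) || is.null(target)) {
      if (!length(carriers)) next
      target <- carriers[sample.int(length(carriers), 1)]
    } else if (!(target %in% carriers)) {
      stop("extra_hgt targets ", target, " for ", gene,
           " but that lineage lost the repertoire and has no residual copy")
    }
    hgt[[length(hgt) + 1L]] <- list(target = target, gene = gene,
                                    multiplier = ev$multiplier %||%
                                      scenario$hgt_multiplier)
  }
  carriers_obs <- names(diazotroph)[diazotroph]
  canonical <- if (length(carriers_obs)) {
    dollo_reconstruct(tree, carriers_obs)
  } else NULL
  structure(list(tree = tree, diazotroph = diazotroph,
                 loss_edges_raw = loss_edges,
                 canonical_gain = if (is.null(canonical)) character() else
                   canonical$gain_clade,
                 canonical_losses = if (is.null(canonical)) list() else
                   canonical$loss_edges,
                 n_canonical_losses = if (is.null(canonical)) NA_integer_ else
                   canonical$n_losses,
                 residuals = residuals, dual = dual, hgt = hgt),
            class = "nif_ground_truth")
}

# add a single tip as a new child of an existing node
.add_tip_at_node <- function(tree, label, node, edge.length) {
  nt <- length(tree$tip.label)
  edge <- tree$edge
  edge[edge > nt] <- edge[edge > nt] + 1L
  node <- node + 1L
  tree$edge <- rbind(edge, c(node, nt + 1L))
  tree$edge.length <- c(tree$edge.length, edge.length)
  tree$tip.label <- c(tree$tip.label, label)
  ape::reorder.phylo(tree, "cladewise")
}

# true gene tree for one gene family: species tree pruned to carriers, with
# dual-set subtree and long HGT attachments applied; attribute `hgt_applied`
# records which transfer events could be represented (needs >= 4 carriers)
.true_gene_tree <- function(truth, gene) {
  diaz <- names(truth$diazotroph)[truth$diazotroph]
  res <- names(truth$residuals)[truth$residuals == gene]
  hgt_here <- Filter(function(ev) ev$gene == gene, truth$hgt)
  carriers <- unique(c(diaz, res, vapply(hgt_here, `[[`, character(1), "target")))
  if (length(carriers) < 2) return(NULL)
  gt <- ape::keep.tip(truth$tree, carriers)
  if (!is.null(truth$dual)) {
    donor <- truth$dual$donor
    if (donor %in% gt$tip.label &&
        all(truth$dual$recipient_leaves %in% gt$tip.label)) {
      sub <- ape::keep.tip(truth$tree, truth$dual$recipient_leaves)
      sub$tip.label <- paste0(sub$tip.label, "__set2")
      donor_idx <- match(donor, gt$tip.label)
      stem <- gt$edge.length[gt$edge[, 2] == donor_idx] / 2
      sub$root.edge <- stem
      gt <- ape::bind.tree(gt, sub, where = donor_idx, position = stem)
    }
  }
  applied <- logical(length(hgt_here))
  for (i in seq_along(hgt_here)) {
    ev <- hgt_here[[i]]
    if (!(ev$target %in% gt$tip.label) || length(gt$tip.label) <= 3) next
    gt <- ape::drop.tip(gt, ev$target)
    nt <- length(gt$tip.label)
    # the multiplier scales the replaced root-to-tip path: a homolog from
    # outside the phylum diverged long before the phylum's own root
    height <- mean(.root_to_tip(gt))
    gt <- .add_tip_at_node(gt, ev$target, nt + 1L,  # the root
                           ev$multiplier * height)
    applied[i] <- TRUE
  }
  attr(gt, "hgt_applied") <- applied
  gt
}

# random protein sequence of given length
.random_protein <- function(len) {
  paste(AA_ALPHABET[sample.int(20L, len, replace = TRUE)], collapse = "")
}

#' Simulate a complete synthetic dataset with ground truth
#'
#' Runs the full generator for one scenario: species tree (plus outgroup for
#' rooting), gain/loss/transfer history, per-gene true gene trees and protein
#' alignments, marker alignments, operon-bearing gene orders with insertions,
#' fusions and dual sets, per-genome proteomes, and the true orthogroup table.
#' Fully deterministic under `scenario$seed`.
#'
#' @param scenario a [nif_scenario()].
#' @return list of class `nif_dataset` with elements `scenario`, `truth`,
#'   `species_tree` (with outgroup when configured), `ingroup_tree`,
#'   `annotations` (named list of gene tables), `proteomes` (named list of
#'   named character vectors), `orthogroups`, `markers` (named list of
#'   alignments), `gene_alignments` (named list per nif gene),
#'   `gene_trees_true`, `catalog` (with the true orthogroup map), `layout`
#'   (true operon layout per genome).
#' @export
simulate_scenario <- function(scenario) {
  set.seed(scenario$seed)
  genes <- names(scenario$nif_lengths)
  tree <- simulate_species_tree(scenario$n_taxa, scenario$birth_rate)
  truth <- simulate_histories(tree, scenario)
  # fusion status per genome (diazotrophs and dual recipients share one flag)
  fused <- stats::setNames(stats::runif(scenario$n_taxa) < scenario$fusion_prob,
                           tree$tip.label)
  fused[!truth$diazotroph] <- FALSE
  truth$fused <- fused

  gene_trees <- list()
  gene_alignments <- list()
  hgt_ok <- rep(FALSE, length(truth$hgt))
  for (g in genes) {
    gt <- .true_gene_tree(truth, g)
    gene_trees[[g]] <- gt
    if (!is.null(gt)) {
      idx <- which(vapply(truth$hgt, function(ev) ev$gene == g, logical(1)))
      hgt_ok[idx] <- attr(gt, "hgt_applied")
      gene_alignments[[g]] <- simulate_sequences(gt, scenario$nif_lengths[[g]],
                                                 scenario$substitution)
    }
  }
  truth$hgt <- truth$hgt[hgt_ok]   # keep only events actually represented
  # outgroup + markers
  full_tree <- tree
  if (scenario$include_outgroup) {
    height <- max(.root_to_tip(tree))
    og <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                         tip.label = "Outgroup",
                         edge.length = height, Nnode = 1L), class = "phylo")
    full_tree <- ape::bind.tree(tree, og, where = length(tree$tip.label) + 1L)
  }
  markers <- list()
  for (m in seq_len(scenario$n_markers)) {
    markers[[sprintf("marker%02d", m)]] <-
      simulate_sequences(full_tree, scenario$marker_length,
                         scenario$substitution)
  }
  # genomes: gene orders, proteomes, orthogroups
  annotations <- list()
  proteomes <- list()
  og_rows <- list()
  layout <- list()
  for (tax in tree$tip.label) {
    built <- .build_genome(tax, truth, scenario, gene_alignments)
    annotations[[tax]] <- built$annotation
    proteomes[[tax]] <- built$proteome
    layout[[tax]] <- built$layout
    if (nrow(built$og)) og_rows[[length(og_rows) + 1L]] <- built$og
  }
  orthogroups <- orthogroup_table(
    if (length(og_rows)) do.call(rbind, og_rows) else
      data.frame(orthogroup_id = character(), genome_id = character(),
                 protein_id = character()))
  og_map <- stats::setNames(c(genes, "nifEN"),
                            paste0("OG_", c(genes, "nifEN")))
  catalog <- nif_catalog(orthogroup_map = og_map)
  structure(list(scenario = scenario, truth = truth,
                 species_tree = full_tree, ingroup_tree = tree,
                 annotations = annotations, proteomes = proteomes,
                 orthogroups = orthogroups, markers = markers,
                 gene_alignments = gene_alignments,
                 gene_trees_true = gene_trees, catalog = catalog,
                 layout = layout),
            class = "nif_dataset")
}

.root_to_tip <- function(tree) {
  nt <- length(tree$tip.label)
  depth <- rep(NA_real_, nt + tree$Nnode)
  depth[nt + 1L] <- 0
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    depth[tr$edge[e, 2]] <- depth[tr$edge[e, 1]] + tr$edge.length[e]
  }
  depth[seq_len(nt)]
}

# assemble one genome: gene order with operon blocks, proteome, orthogroup rows
.build_genome <- function(tax, truth, scenario, gene_alignments) {
  templates <- operon_templates()
  diaz <- truth$diazotroph[[tax]]
  dual_member <- !is.null(truth$dual) && tax %in% truth$dual$recipient_leaves
  residual <- truth$residuals[tax]
  n_filler <- scenario$n_filler
  seq_for <- function(gene, set2 = FALSE) {
    tip <- if (set2) paste0(tax, "__set2") else tax
    aln <- gene_alignments[[gene]]
    if (is.null(aln) || !(tip %in% names(aln))) .random_protein(scenario$nif_lengths[[gene]])
    else unname(aln[tip])
  }
  make_block <- function(template, set2 = FALSE) {
    members <- templates[[template]]
    items <- list()
    skip_next <- FALSE
    for (i in seq_along(members)) {
      if (skip_next) { skip_next <- FALSE; next }
      g <- members[i]
      if (truth$fused[[tax]] && g == "nifE" && i < length(members) &&
          members[i + 1] == "nifN") {
        items[[length(items) + 1L]] <- list(
          gene = "nifEN", seq = paste0(seq_for("nifE", set2), seq_for("nifN", set2)))
        skip_next <- TRUE
      } else {
        items[[length(items) + 1L]] <- list(gene = g, seq = seq_for(g, set2))
      }
      if (i < length(members) && stats::runif(1) < scenario$insertion_prob) {
        for (f in seq_len(sample.int(2L, 1))) {
          items[[length(items) + 1L]] <- list(gene = NA_character_,
                                              seq = .random_protein(250L))
        }
      }
    }
    items
  }
  blocks <- list()
  if (diaz) {
    set_specs <- list(list(set = "set1", set2 = FALSE))
    if (dual_member) set_specs <- c(set_specs, list(list(set = "set2", set2 = TRUE)))
    for (spec in set_specs) {
      for (tn in names(templates)[sample.int(4)]) {
        blocks[[length(blocks) + 1L]] <- list(template = tn, set = spec$set,
                                              items = make_block(tn, spec$set2))
      }
    }
  } else if (!is.na(residual)) {
    blocks[[length(blocks) + 1L]] <- list(
      template = NA_character_, set = "residual",
      items = list(list(gene = residual, seq = seq_for(residual))))
  }
  # anchor filler indices (block inserted after that filler), >= 8 fillers
  # apart; set1 blocks in the first third, set2 in the last third, so dual
  # sets sit beyond the dual-set separation threshold
  pick_anchors <- function(lo, hi, k) {
    spacing <- 8L
    usable <- hi - lo - spacing * (k - 1L)
    if (usable < 1L) {    # degenerate small genomes: evenly spaced fallback
      return(as.integer(round(seq(lo, hi, length.out = k))))
    }
    lo + sort(sample.int(usable, k)) - 1L + spacing * (seq_len(k) - 1L)
  }
  n_blocks <- length(blocks)
  anchors <- integer(n_blocks)
  if (n_blocks) {
    sets <- vapply(blocks, `[[`, character(1), "set")
    n1 <- sum(sets != "set2")
    if (n1) anchors[sets != "set2"] <- pick_anchors(3L, max(4L, n_filler %/% 3L), n1)
    n2 <- sum(sets == "set2")
    if (n2) anchors[sets == "set2"] <-
        pick_anchors(min(n_filler - 2L, 2L * (n_filler %/% 3L)),
                     n_filler - 1L, n2)
  }
  # assemble gene list, tracking 0-based positions of block members
  genes_out <- list()
  lay <- list()
  for (f in seq_len(n_filler)) {
    genes_out[[length(genes_out) + 1L]] <- list(gene = NA_character_,
                                                seq = .random_protein(
                                                  sample(150:350, 1)))
    for (b in which(anchors == f)) {
      pos0 <- length(genes_out)           # 0-based ordinal of first block item
      for (it in blocks[[b]]$items) genes_out[[length(genes_out) + 1L]] <- it
      glab <- vapply(blocks[[b]]$items, `[[`, character(1), "gene")
      keepg <- !is.na(glab)
      lay[[length(lay) + 1L]] <- list(
        template = blocks[[b]]$template, set = blocks[[b]]$set,
        genes = glab[keepg],
        ordinals = (pos0 + seq_along(glab) - 1L)[keepg])
    }
  }
  n <- length(genes_out)
  lens <- vapply(genes_out, function(it) nchar(it$seq), integer(1))
  gaps <- sample(20:200, n, replace = TRUE)
  starts <- cumsum(c(1L, (3L * lens + gaps)[-n]))
  labels <- vapply(genes_out, function(it) it$gene, character(1))
  locus <- sprintf("%s_%05d", tax, seq_len(n))
  ann <- as_gene_table(data.frame(
    genome_id = tax, contig_id = "c1", start = starts,
    end = starts + 3L * lens - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    locus_tag = locus, gene_label = labels, stringsAsFactors = FALSE))
  proteome <- stats::setNames(vapply(genes_out, `[[`, character(1), "seq"), locus)
  isnif <- which(!is.na(labels))
  og <- if (length(isnif)) {
    data.frame(orthogroup_id = paste0("OG_", labels[isnif]),
               genome_id = rep(tax, length(isnif)),
               protein_id = locus[isnif], stringsAsFactors = FALSE)
  } else {
    data.frame(orthogroup_id = character(), genome_id = character(),
               protein_id = character(), stringsAsFactors = FALSE)
  }
  list(annotation = ann, proteome = proteome, og = og, layout = lay)
}
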