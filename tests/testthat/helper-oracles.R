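# Independent brute-force oracles and tiny fixture builders used across tests.

# gene table with given labels at consecutive coordinates (one contig each,
# NA label = non-nif filler); nif_gene filled directly so operon tests do not
# depend on orthogroup plumbing
toy_annotation <- function(labels, genome = "G1", contig = "c1") {
  n <- length(labels)
  ann <- as_gene_table(data.frame(
    genome_id = genome, contig_id = contig,
    start = seq(1L, by = 1000L, length.out = n),
    end = seq(500L, by = 1000L, length.out = n),
    strand = "+",
    locus_tag = sprintf("%s_%s_%03d", genome, contig, seq_len(n)),
    gene_label = labels, stringsAsFactors = FALSE))
  tag_direct(ann)
}

tag_direct <- function(ann, catalog = nif_catalog()) {
  valid <- c(catalog$gene_names, names(catalog$fused_names))
  ann$nif_gene <- ifelse(!is.na(ann$gene_label) & ann$gene_label %in% valid,
                         ann$gene_label, NA_character_)
  ann$nif_evidence <- ifelse(is.na(ann$nif_gene), NA_character_, "orthogroup")
  ann
}

# multi-contig toy annotation: labels_list is a named list contig -> labels
toy_annotation_multi <- function(labels_list, genome = "G1") {
  parts <- lapply(names(labels_list), function(ct) {
    labs <- labels_list[[ct]]
    data.frame(genome_id = genome, contig_id = ct,
               start = seq(1L, by = 1000L, length.out = length(labs)),
               end = seq(500L, by = 1000L, length.out = length(labs)),
               strand = "+",
               locus_tag = sprintf("%s_%s_%03d", genome, ct,
                                   seq_along(labs)),
               gene_label = labs, stringsAsFactors = FALSE)
  })
  tag_direct(as_gene_table(do.call(rbind, parts)))
}

random_nif_table <- function(max_genes = 30, n_contigs = 1) {
  n <- sample(5:max_genes, 1)
  contig <- sort(sample(paste0("c", seq_len(n_contigs)), n, replace = TRUE))
  genes <- nif_catalog()$gene_names
  labels <- ifelse(stats::runif(n) < 0.35, sample(genes, n, replace = TRUE),
                   NA_character_)
  toy_annotation_multi(split(labels, contig))
}

# brute-force clustering oracle: exhaustive pairwise merging to fixed point,
# then iterative bridging of singletons flanked by multi-gene groups
oracle_clusters <- function(annotation, config) {
  nif <- annotation[!is.na(annotation$nif_gene) & !annotation$pseudo, ,
                    drop = FALSE]
  out <- list()
  for (ct in unique(nif$contig_id)) {
    groups <- as.list(sort(nif$ordinal[nif$contig_id == ct]))
    repeat {
      merged <- FALSE
      for (i in seq_along(groups)) {
        for (j in seq_along(groups)) {
          if (i >= j) next
          gap <- min(vapply(groups[[i]], function(a)
            min(abs(a - groups[[j]]) - 1L), numeric(1)))
          if (gap < config$max_gap) {
            groups[[i]] <- sort(c(groups[[i]], groups[[j]]))
            groups[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
    if (config$bridging_enabled) {
      repeat {
        groups <- groups[order(vapply(groups, min, numeric(1)))]
        sizes <- lengths(groups)
        left <- c(0L, sizes[-length(sizes)])
        right <- c(sizes[-1], 0L)
        hit <- which(sizes == 1 & left > 1 & right > 1)
        if (!length(hit)) break
        i <- hit[1]
        groups[[i - 1]] <- sort(c(groups[[i - 1]], groups[[i]], groups[[i + 1]]))
        groups[[i]] <- groups[[i + 1]] <- NULL
      }
    }
    out[[ct]] <- lapply(groups[order(vapply(groups, min, numeric(1)))], sort)
  }
  if (!length(out)) return(out)
  out[order(names(out))]
}

cluster_ordinals <- function(clusters) {
  out <- list()
  for (cl in clusters) {
    out[[cl$contig_id]] <- c(out[[cl$contig_id]], list(sort(cl$members$ordinal)))
  }
  out <- lapply(out, function(gs) gs[order(vapply(gs, min, numeric(1)))])
  if (!length(out)) return(out)
  out[order(names(out))]
}

# brute-force Dollo minimum: smallest number of loss edges below the gain node
# whose subtended leaves together equal the absent set (leaf-set bitmasks)
oracle_dollo_min <- function(tree, present) {
  nt <- length(tree$tip.label)
  gain <- if (length(present) == 1) match(present, tree$tip.label) else
    ape::getMRCA(tree, present)
  node_tips <- c(as.list(seq_len(nt)),
                 phangorn::Descendants(tree, (nt + 1):(nt + tree$Nnode), "tips"))
  mask <- vapply(node_tips, function(tp) sum(2^(tp - 1)), numeric(1))
  below <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    c(kids, unlist(lapply(kids, below)))
  }
  cand <- below(gain)
  gain_leaves <- node_tips[[gain]]
  absent <- setdiff(gain_leaves, match(present, tree$tip.label))
  if (!length(absent)) return(0L)
  absent_mask <- sum(2^(absent - 1))
  for (k in seq_len(length(absent))) {
    combos <- utils::combn(cand, k)
    for (ci in seq_len(ncol(combos))) {
      sel <- combos[, ci]
      u <- sum(2^(unique(unlist(node_tips[sel])) - 1))
      if (u == absent_mask) return(k)
    }
  }
  length(absent)
}

# exhaustive monophyly oracle: a group is monophyletic iff some node's tip set
# equals it; smallest containing clade found by scanning all nodes
oracle_monophyly <- function(tree, group) {
  nt <- length(tree$tip.label)
  node_tips <- c(as.list(tree$tip.label),
                 lapply(phangorn::Descendants(tree, (nt + 1):(nt + tree$Nnode),
                                              "tips"),
                        function(i) tree$tip.label[i]))
  covering <- Filter(function(tp) all(group %in% tp), node_tips)
  smallest <- covering[[which.min(lengths(covering))]]
  list(monophyletic = length(smallest) == length(group),
       intruders = sort(setdiff(smallest, group)))
}

# does the unrooted tree contain the AB|CD split?
.split_ab_cd <- function(tree) {
  any(vapply(tree_splits(tree), function(k) {
    s <- strsplit(k, "\r", fixed = TRUE)[[1]]
    setequal(s, c("A", "B")) || setequal(s, c("C", "D"))
  }, logical(1)))
}

random_resolved_tree <- function(n) {
  t <- ape::rtree(n, rooted = TRUE)
  t$tip.label <- sprintf("t%02d", seq_len(n))
  t
}

# paralog-selection case: a species tree, sequences evolved on it, and for one
# focal genome two candidate copies — its vertical sequence and a copy grafted
# into a foreign clade (next to a distant, non-basal donor lineage; a graft at
# the root would not be inside any clade and carries no discordance signal)
simulate_paralog_case <- function(seed, n_taxa = 12, len = 300, rate = 0.3) {
  set.seed(seed)
  sp <- simulate_species_tree(n_taxa, 1)
  pd <- ape::cophenetic.phylo(sp)
  nt <- length(sp$tip.label)
  root <- nt + 1L
  parent_of <- function(lbl) sp$edge[sp$edge[, 2] == match(lbl, sp$tip.label), 1]
  nonbasal <- sp$tip.label[vapply(sp$tip.label,
                                  function(l) parent_of(l) != root, logical(1))]
  focal <- nonbasal[1]
  donors <- setdiff(nonbasal, focal)
  # foreign = topologically distant: long branches can make a topologically
  # adjacent cherry the patristically farthest, which carries no discordance
  unit <- sp
  unit$edge.length <- rep(1, nrow(sp$edge))
  topo <- ape::cophenetic.phylo(unit)
  donor <- donors[order(-topo[focal, donors], -pd[focal, donors])][1]
  donor_idx <- match(donor, sp$tip.label)
  donor_parent <- sp$edge[sp$edge[, 2] == donor_idx, 1]
  donor_pend <- sp$edge.length[sp$edge[, 2] == donor_idx]
  gt <- nifloss:::.add_tip_at_node(sp, "copy2", donor_parent, donor_pend)
  aln <- simulate_sequences(gt, len, rate)
  cohort <- aln[setdiff(sp$tip.label, focal)]
  list(species_tree = sp, focal = focal,
       vertical = list(gene_name = "nifB", genome_id = focal,
                       locus_tag = "vert", sequence = unname(aln[focal])),
       grafted = list(gene_name = "nifB", genome_id = focal,
                      locus_tag = "graf", sequence = unname(aln[["copy2"]])),
       cohort = cohort)
}

# end-to-end loss/HGT scenario evaluation: simulate one scenario with an
# injected extra-phylum transfer, run the pipeline against the true species
# tree, and score transfer detection plus loss-history recovery
hgt_scenario_metrics <- function(seed) {
  sc <- nif_scenario(seed = seed, n_taxa = 20, loss_prob_per_edge = 0.05,
                     n_random_hgt = 1, hgt_multiplier = 5)
  ds <- simulate_scenario(sc)
  res <- run_nif_pipeline(ds, species_tree = ds$ingroup_tree)
  hc <- res$report$hgt_calls
  inj_keys <- vapply(ds$truth$hgt, function(ev) paste(ev$gene, ev$target),
                     character(1))
  all_keys <- paste(hc$gene, hc$taxon)
  extra_keys <- all_keys[hc$verdict == "extra_phylum_hgt"]
  tp <- sum(inj_keys %in% extra_keys)
  fp <- sum(!(extra_keys %in% inj_keys))
  h <- res$histories$diazotroph
  truth_has <- length(ds$truth$canonical_gain) > 0
  recovered <- if (!truth_has) is.null(h) else {
    !is.null(h) && setequal(h$gain_clade, ds$truth$canonical_gain) &&
      h$n_losses == ds$truth$n_canonical_losses
  }
  c(tp = tp, fn = length(inj_keys) - tp, fp = fp,
    n_vert = sum(!(all_keys %in% inj_keys)), recovered = as.numeric(recovered))
}
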