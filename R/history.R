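#' Dollo reconstruction of gene losses on a species tree
#'
#' Under the Dollo assumption (one gain, any number of losses) the gain node
#' is the most recent common ancestor of the present taxa (or a user-pinned
#' ancestor of them) and the minimal loss set marks each maximal absent clade
#' below the gain with one loss. The reported loss count is the parsimony
#' minimum. The number of gains that a no-loss model would need (maximal
#' fully-present clades) is reported alongside for comparison.
#'
#' @param species_tree rooted `phylo`.
#' @param present_taxa non-empty character vector of tips carrying the gene.
#' @param gain_node optional pinned gain node (ape node number); must be an
#'   ancestor of every present taxon.
#' @return list of class `loss_history`: `gain_node`, `gain_clade` (sorted
#'   tips below the gain), `loss_edges` (list of sorted tip sets, one per lost
#'   clade), `n_losses`, `n_gains_no_loss`.
#' @export
dollo_reconstruct <- function(species_tree, present_taxa, gain_node = NULL) {
  present_taxa <- unique(present_taxa)
  if (!length(present_taxa)) stop("present_taxa is empty")
  missing <- setdiff(present_taxa, species_tree$tip.label)
  if (length(missing)) stop("present taxa absent from tree: ",
                            paste(missing, collapse = ", "))
  nt <- length(species_tree$tip.label)
  sets <- .node_tip_sets(species_tree)
  mrca <- if (length(present_taxa) == 1) {
    match(present_taxa, species_tree$tip.label)
  } else ape::getMRCA(species_tree, present_taxa)
  if (is.null(gain_node)) {
    gain_node <- mrca
  } else if (!all(present_taxa %in% sets[[gain_node]])) {
    stop("profile contradicts pinned gain: present taxa outside the gain clade")
  }
  gain_clade <- sets[[gain_node]]
  present <- gain_clade %in% present_taxa
  names(present) <- gain_clade
  # postorder all-absent / all-present flags for nodes under the gain
  all_absent <- all_present <- rep(NA, nt + species_tree$Nnode)
  for (i in seq_len(nt)) {
    all_absent[i] <- !(species_tree$tip.label[i] %in% present_taxa)
    all_present[i] <- !all_absent[i]
  }
  for (e in ape::postorder(species_tree)) {
    p <- species_tree$edge[e, 1]; ch <- species_tree$edge[e, 2]
    all_absent[p] <- if (is.na(all_absent[p])) all_absent[ch]
      else all_absent[p] && all_absent[ch]
    all_present[p] <- if (is.na(all_present[p])) all_present[ch]
      else all_present[p] && all_present[ch]
  }
  under <- function(node) {
    # nodes strictly below `node`
    out <- integer(0)
    stack <- species_tree$edge[species_tree$edge[, 1] == node, 2]
    while (length(stack)) {
      x <- stack[1]; stack <- stack[-1]
      out <- c(out, x)
      stack <- c(stack, species_tree$edge[species_tree$edge[, 1] == x, 2])
    }
    out
  }
  below <- under(gain_node)
  parent_of <- function(node) species_tree$edge[species_tree$edge[, 2] == node, 1]
  loss_nodes <- below[vapply(below, function(x)
    all_absent[x] && !all_absent[parent_of(x)], logical(1))]
  gain_nodes_alt <- c(gain_node, below)[vapply(c(gain_node, below), function(x) {
    if (!all_present[x]) return(FALSE)
    if (x == gain_node) return(TRUE)
    !all_present[parent_of(x)]
  }, logical(1))]
  structure(list(
    gain_node = gain_node,
    gain_clade = gain_clade,
    loss_edges = lapply(loss_nodes, function(x) sets[[x]]),
    n_losses = length(loss_nodes),
    n_gains_no_loss = length(gain_nodes_alt)),
    class = "loss_history")
}

#' @export
print.loss_history <- function(x, ...) {
  cat(sprintf("<loss_history> gain over {%s}; %d loss(es); %d gain(s) if losses forbidden\n",
              paste(x$gain_clade, collapse = ","), x$n_losses, x$n_gains_no_loss))
  invisible(x)
}

#' Classify one taxon's gene history
#'
#' Adjudicates vertical inheritance vs horizontal transfer for one gene in one
#' taxon, combining two signals computed on the gene tree:
#' \itemize{
#' \item extra-phylum transfer: the taxon's external branch (or its subtending
#'   internal branch) is a branch-length outlier in the gene tree, attaches
#'   root-proximally, and the anomaly is gene-specific — the taxon's pendant
#'   branch in the species tree is NOT itself an outlier (an intrinsically
#'   long basal lineage is long in every tree and is explained by vertical
#'   inheritance); this is the long-branch-near-the-root pattern of foreign
#'   homologs;
#' \item intra-phylum transfer: no long branch, but removing the taxon lowers
#'   the pruned Robinson-Foulds distance between gene tree and species tree by
#'   at least `incongruence_margin`;
#' \item vertical: neither signal; unresolved: a long branch that does not
#'   attach root-proximally.
#' }
#'
#' @param taxon tip label (must be in the gene tree).
#' @param gene_name gene family name (carried through to the verdict).
#' @param gene_tree `phylo`; tips named by genome id (a `__set2` suffix marks
#'   second operon sets, which are ignored for congruence).
#' @param species_tree rooted `phylo` of all genomes.
#' @param outliers optional precomputed outlier reports for the rooted gene
#'   tree: a list with elements `external` and `internal`, each a
#'   [branch_length_outliers()] data frame for that scope. Scoping matters:
#'   pendant edges are systematically longer than internal ones, so each class
#'   is compared against its own length distribution.
#' @param k outlier threshold, see [branch_length_outliers()].
#' @param incongruence_margin minimum RF improvement on taxon removal that
#'   counts as placement incongruence (default 2).
#' @param root_taxa taxa used to root an unrooted gene tree (normally the
#'   earliest-diverging carrier clade of the species tree, see
#'   [root_gene_tree()]); midpoint rooting is the fallback.
#' @param species_outliers optional precomputed [species_tree_outliers()]
#'   report for the species tree pruned to this gene tree's carriers (the
#'   gene-specificity control).
#' @return list of class `gene_history_call`: taxon, gene_name, verdict
#'   ("vertical", "intra_phylum_hgt", "extra_phylum_hgt", "unresolved"),
#'   and evidence (z, root_proximal, rf_with, rf_without, rf_improvement).
#' @export
classify_gene_history <- function(taxon, gene_name, gene_tree, species_tree,
                                  outliers = NULL, k = 3,
                                  incongruence_margin = 2, root_taxa = NULL,
                                  species_outliers = NULL) {
  if (!(taxon %in% gene_tree$tip.label)) {
    stop("taxon ", taxon, " absent from gene tree")
  }
  rooted <- if (ape::is.rooted(gene_tree)) gene_tree else
    root_gene_tree(gene_tree, root_taxa)
  if (is.null(outliers)) outliers <- gene_tree_outliers(rooted, k = k)
  nt <- length(rooted$tip.label)
  tip_idx <- match(taxon, rooted$tip.label)
  oe <- outliers$external
  oi <- outliers$internal
  pend <- oe[!is.na(oe$tip) & oe$tip == taxon, , drop = FALSE]
  parent_node <- rooted$edge[rooted$edge[, 2] == tip_idx, 1]
  sub <- if (is.null(oi)) oe[0, ] else
    oi[oi$child == parent_node, , drop = FALSE]
  # gene-specificity control: the same statistic on the species tree pruned
  # to the gene tree's carriers. A lineage (or basal cherry) that is equally
  # anomalous there is long in every tree, which vertical inheritance explains.
  plain_tips <- grep("__set2$", rooted$tip.label, invert = TRUE, value = TRUE)
  if (is.null(species_outliers)) {
    species_outliers <- species_tree_outliers(species_tree, plain_tips, k = k)
  }
  sp_pend <- species_outliers$external
  sp_pend <- if (is.null(sp_pend)) pend[0, ] else
    sp_pend[!is.na(sp_pend$tip) & sp_pend$tip == taxon, , drop = FALSE]
  # the species-side anomaly excuses the gene-side one only when it is of
  # comparable magnitude; a gene z far beyond the species z is gene-specific
  species_long <- nrow(sp_pend) > 0 && any(sp_pend$flagged) &&
    (!nrow(pend) || max(pend$z) <= max(sp_pend$z) + k)
  pend_long <- any(pend$flagged) && !species_long
  # internal (cherry-stem) route: the paired-transfer signature — the stem
  # subtending the taxon and one sibling is anomalous in the gene tree but
  # not for the same pair in the species tree
  cherry <- .node_tip_sets(rooted)[[parent_node]]
  sub_long <- FALSE
  if (any(sub$flagged) && length(cherry) <= 2) {
    sp_stem_flagged <- FALSE
    sp_tree <- species_outliers$tree
    if (!is.null(sp_tree) && all(cherry %in% sp_tree$tip.label) &&
        length(cherry) == 2) {
      sp_sets <- .node_tip_sets(sp_tree)
      hit <- which(vapply(sp_sets, function(s) setequal(s, cherry), logical(1)))
      hit <- hit[hit > length(sp_tree$tip.label)]
      if (length(hit)) {           # the pair is a species-tree cherry too
        oi_sp <- species_outliers$internal
        if (!is.null(oi_sp)) {
          stem <- oi_sp[oi_sp$child == hit[1], , drop = FALSE]
          sp_stem_flagged <- nrow(stem) > 0 && any(stem$flagged)
        }
      } else {
        sp_stem_flagged <- TRUE    # pair absent from the species tree:
      }                            # incongruence, not the long-stem signature
    }
    sub_long <- !sp_stem_flagged
  }
  long <- pend_long || sub_long
  rootprox <- (nrow(pend) && any(pend$flagged & pend$root_proximal) &&
                 pend_long) ||
    (nrow(sub) && any(sub$flagged & sub$root_proximal) && sub_long)
  evidence <- list(z = if (nrow(pend)) pend$z[1] else NA_real_,
                   species_z = if (nrow(sp_pend)) sp_pend$z[1] else NA_real_,
                   root_proximal = rootprox)
  # congruence: shared plain-labelled taxa
  plain <- grep("__set2$", gene_tree$tip.label, invert = TRUE, value = TRUE)
  shared <- intersect(plain, species_tree$tip.label)
  verdict <- NULL
  if (long && rootprox) {
    verdict <- "extra_phylum_hgt"
  } else if (long) {
    verdict <- "unresolved"
  }
  rf_with <- rf_without <- NA_integer_
  if (is.null(verdict)) {
    if (length(shared) >= 5 && taxon %in% shared) {
      g <- ape::keep.tip(gene_tree, shared)
      s <- ape::keep.tip(species_tree, shared)
      gs <- tree_splits(g); ss <- tree_splits(s)
      rf_with <- sum(!(gs %in% ss)) + sum(!(ss %in% gs))
      rf_without <- .rf_project_drop(gs, ss, sort(shared), taxon)
      verdict <- if ((rf_with - rf_without) >= incongruence_margin)
        "intra_phylum_hgt" else "vertical"
    } else {
      verdict <- "vertical"
    }
  }
  evidence$rf_with <- rf_with
  evidence$rf_without <- rf_without
  evidence$rf_improvement <- rf_with - rf_without
  structure(list(taxon = taxon, gene_name = gene_name, verdict = verdict,
                 evidence = evidence),
            class = "gene_history_call")
}

#' Per-scope branch-length outlier reports for a gene tree
#'
#' Computes [branch_length_outliers()] separately for pendant and internal
#' edges, so each edge class is judged against its own length distribution
#' (pendant edges are systematically longer than internal ones; pooling the
#' two inflates pendant z-scores). The internal report is `NULL` for trees
#' with fewer than four internal edges.
#'
#' @param rooted_gene_tree a rooted `phylo`.
#' @param k flagging threshold, see [branch_length_outliers()].
#' @return list with elements `external` and `internal`.
#' @export
gene_tree_outliers <- function(rooted_gene_tree, k = 3) {
  ext <- suppressWarnings(
    branch_length_outliers(rooted_gene_tree, k = k, scope = "external"))
  int <- tryCatch(suppressWarnings(
    branch_length_outliers(rooted_gene_tree, k = k, scope = "internal")),
    error = function(e) NULL)
  list(external = ext, internal = int)
}

#' Outlier reports for the species tree restricted to a carrier set
#'
#' The gene-specificity control of [classify_gene_history()] compares each
#' branch-length statistic on the gene tree with the same statistic on the
#' species tree pruned to the identical taxon set, so the two robust z-scores
#' are computed over comparable distributions.
#'
#' @param species_tree rooted `phylo`.
#' @param carriers tips to keep.
#' @param k flagging threshold.
#' @return list with `external`, `internal` (outlier reports or `NULL`) and
#'   `tree` (the pruned species tree).
#' @export
species_tree_outliers <- function(species_tree, carriers, k = 3) {
  keep <- intersect(carriers, species_tree$tip.label)
  if (length(keep) < 4) return(list(external = NULL, internal = NULL, tree = NULL))
  pruned <- ape::keep.tip(species_tree, keep)
  out <- gene_tree_outliers(pruned, k = k)
  out$tree <- pruned
  out
}

#' Root a gene tree on an outgroup clade, with midpoint fallback
#'
#' Gene trees carry no explicit outgroup, so the earliest-diverging carrier
#' clade of the rooted species tree serves as the rooting anchor (mirroring
#' the use of the first-diverging diazotrophs as the outgroup in nif gene
#' trees). When those taxa are absent or not cladable in the gene tree, the
#' tree is midpoint rooted instead. Rooting matters for the root-proximal
#' criterion of [classify_gene_history()]: midpoint rooting alone would place
#' the root on any dominant long branch and make the criterion vacuous.
#'
#' @param gene_tree an unrooted `phylo`.
#' @param root_taxa candidate outgroup taxa (a superset is fine; the
#'   intersection with the gene tree's tips is used).
#' @return a rooted `phylo`.
#' @export
root_gene_tree <- function(gene_tree, root_taxa = NULL) {
  if (ape::is.rooted(gene_tree)) return(gene_tree)
  og <- intersect(root_taxa, gene_tree$tip.label)
  if (length(og) && length(og) < length(gene_tree$tip.label) - 1) {
    out <- tryCatch(root_at_outgroup(gene_tree, og), error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  phangorn::midpoint(gene_tree)
}

#' Earliest-diverging clade of a rooted species tree
#'
#' The smaller of the two clades meeting at the root; used as the rooting
#' anchor for gene trees.
#'
#' @param species_tree rooted `phylo`.
#' @return character vector of tip labels.
#' @export
basal_clade <- function(species_tree) {
  nt <- length(species_tree$tip.label)
  sets <- .node_tip_sets(species_tree)
  kids <- species_tree$edge[species_tree$edge[, 1] == nt + 1L, 2]
  clades <- lapply(kids, function(x) sets[[x]])
  clades[[which.min(lengths(clades))]]
}

#' Presence profile of an operon template from operon calls
#'
#' @param calls list of `operon_call` across genomes.
#' @param template template name.
#' @param min_members minimum number of template members a call needs to count
#'   as operonic presence (default 2: a lone residual gene is not an operon).
#' @return character vector of genomes carrying the template.
#' @export
presence_profile <- function(calls, template, min_members = 2) {
  hit <- vapply(calls, function(cl) {
    cl$template == template &&
      length(intersect(unlist(nif_components(cl$members$nif_gene)),
                       operon_templates()[[template]])) >= min_members
  }, logical(1))
  sort(unique(vapply(calls[hit], function(cl) cl$genome_id, character(1))))
}

#' Summarise gene histories and loss reconstructions into a scenario report
#'
#' Produces the per-template table of gain node and loss count, the tally of
#' HGT verdicts, per-genome diazotroph verdicts (all four templates present
#' with at least two members each), the non-diazotroph homolog carriers, and a
#' machine-readable verdict on the headline hypothesis (single ancestral gain
#' plus independent losses vs transfer-dominated histories).
#'
#' @param calls list of `gene_history_call`.
#' @param loss_histories named list of `loss_history` (per template and/or the
#'   whole-repertoire "diazotroph" history).
#' @param diazotroph named logical vector: genome -> diazotroph verdict.
#' @param carriers optional data frame (genome_id, gene) of nif homologs found
#'   in non-diazotroph genomes.
#' @param set_identity optional output of [assign_set_identity()].
#' @return list of class `nif_history_report`.
#' @export
summarize_history <- function(calls, loss_histories, diazotroph,
                              carriers = NULL, set_identity = NULL) {
  verdicts <- if (length(calls)) {
    data.frame(taxon = vapply(calls, `[[`, character(1), "taxon"),
               gene = vapply(calls, `[[`, character(1), "gene_name"),
               verdict = vapply(calls, `[[`, character(1), "verdict"),
               stringsAsFactors = FALSE)
  } else data.frame(taxon = character(), gene = character(),
                    verdict = character())
  templates <- if (length(loss_histories)) {
    data.frame(
      template = names(loss_histories),
      gain_clade = vapply(loss_histories, function(h)
        if (is.null(h)) "" else paste(h$gain_clade, collapse = ","), character(1)),
      n_losses = vapply(loss_histories, function(h)
        if (is.null(h)) NA_integer_ else h$n_losses, integer(1)),
      n_gains_no_loss = vapply(loss_histories, function(h)
        if (is.null(h)) NA_integer_ else h$n_gains_no_loss, integer(1)),
      stringsAsFactors = FALSE)
  } else data.frame(template = character(), gain_clade = character(),
                    n_losses = integer(), n_gains_no_loss = integer())
  n_extra <- sum(verdicts$verdict == "extra_phylum_hgt")
  n_intra <- sum(verdicts$verdict == "intra_phylum_hgt") +
    if (!is.null(set_identity)) sum(set_identity$identity == "nif2" &
                                      set_identity$set_label == "set2") else 0L
  rep_hist <- loss_histories[["diazotroph"]]
  headline <- if (!is.null(rep_hist)) {
    sprintf("single ancestral gain + %d independent losses; extra-phylum transfers among operon genes: %d; intra-phylum transfer events: %d",
            rep_hist$n_losses, n_extra, n_intra)
  } else if (!any(diazotroph)) {
    "nif repertoire absent from every genome"
  } else {
    "no repertoire history reconstructed"
  }
  structure(list(templates = templates,
                 diazotroph = diazotroph[order(names(diazotroph))],
                 hgt_calls = verdicts[order(verdicts$gene, verdicts$taxon), ,
                                      drop = FALSE],
                 carriers = carriers,
                 set_identity = set_identity,
                 n_extra_phylum = n_extra,
                 n_intra_phylum = n_intra,
                 headline = headline),
            class = "nif_history_report")
}

#' Render a history report as plain text
#'
#' @param x a `nif_history_report`.
#' @param ... unused.
#' @return character vector of lines (deterministic for identical inputs).
#' @export
format.nif_history_report <- function(x, ...) {
  lines <- c("nif gene history report",
             "=======================",
             paste0("headline: ", x$headline), "")
  lines <- c(lines, "template histories (gain clade; minimal losses; gains if losses forbidden):")
  for (i in seq_len(nrow(x$templates))) {
    t <- x$templates[i, ]
    lines <- c(lines, sprintf("  %-11s losses=%s gains_no_loss=%s gain={%s}",
                              t$template, t$n_losses, t$n_gains_no_loss,
                              t$gain_clade))
  }
  lines <- c(lines, "", sprintf("diazotrophs: %d / %d genomes",
                                sum(x$diazotroph), length(x$diazotroph)))
  lines <- c(lines, paste0("  ", names(x$diazotroph), ": ",
                           ifelse(x$diazotroph, "diazotroph", "non-diazotroph")))
  if (!is.null(x$carriers) && nrow(x$carriers)) {
    lines <- c(lines, "", "non-diazotroph nif homolog carriers:")
    lines <- c(lines, sprintf("  %s: %s", x$carriers$genome_id, x$carriers$gene))
  }
  hv <- x$hgt_calls[x$hgt_calls$verdict != "vertical", , drop = FALSE]
  lines <- c(lines, "", sprintf("gene-history verdicts: %d calls (%d extra-phylum, %d intra-phylum)",
                                nrow(x$hgt_calls), x$n_extra_phylum,
                                sum(x$hgt_calls$verdict == "intra_phylum_hgt")))
  if (nrow(hv)) {
    lines <- c(lines, sprintf("  %s %s: %s", hv$gene, hv$taxon, hv$verdict))
  }
  if (!is.null(x$set_identity) && nrow(x$set_identity)) {
    lines <- c(lines, "", "dual operon set identities:")
    si <- x$set_identity
    lines <- c(lines, sprintf("  %s %s -> %s", si$genome_id, si$set_label,
                              si$identity))
  }
  lines
}

#' @export
print.nif_history_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}
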