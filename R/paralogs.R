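#' Score one paralog candidate by species-tree congruence
#'
#' Builds a gene tree ([protein_distance()] + [neighbor_joining()]) from the
#' single-copy cohort plus the candidate (the candidate tip is labelled with
#' its genome id), prunes the species tree to the same genomes, and scores the
#' candidate by the Robinson-Foulds distance between the two trees. Candidates
#' are scored one at a time against the cohort, so a transferred paralog
#' cannot distort the placement of the copy under evaluation.
#'
#' @param candidate list with `gene_name`, `genome_id`, `locus_tag`,
#'   `sequence` (aligned to the cohort).
#' @param cohort named character vector: genome_id -> aligned sequence for the
#'   single-copy genomes (>= 3 of them).
#' @param species_tree a `phylo` containing all cohort genomes and the
#'   candidate's genome.
#' @param model distance model, see [protein_distance()].
#' @return list with `locus_tag`, `rf`, and `external_branch` (the candidate
#'   tip's pendant length in the gene tree, the first tie-breaker).
#' @export
score_candidate <- function(candidate, cohort, species_tree, model = "poisson") {
  if (length(cohort) < 3) stop("insufficient cohort: need >= 3 other genomes")
  aln <- c(cohort, stats::setNames(candidate$sequence, candidate$genome_id))
  if (anyDuplicated(names(aln))) {
    stop("cohort already contains the candidate genome ", candidate$genome_id)
  }
  gene_tree <- neighbor_joining(protein_distance(aln, model))
  sp <- ape::keep.tip(species_tree, names(aln))
  nt <- length(gene_tree$tip.label)
  tip <- match(candidate$genome_id, gene_tree$tip.label)
  pend <- gene_tree$edge.length[gene_tree$edge[, 2] == tip]
  list(locus_tag = candidate$locus_tag,
       rf = robinson_foulds(gene_tree, sp),
       external_branch = pend)
}

#' Select one gene copy among within-operon paralogs
#'
#' The copy whose gene tree is most congruent with the species tree (minimal
#' Robinson-Foulds distance, see [score_candidate()]) wins. Ties are broken by
#' (1) the shorter external branch in the gene tree, then (2) lexicographic
#' locus_tag. A single candidate is returned unscored. The choice is invariant
#' to the input order of the candidates.
#'
#' @param candidates list of candidates (see [score_candidate()]), sharing
#'   gene_name and genome_id.
#' @param cohort,species_tree,model as in [score_candidate()].
#' @return list with `selected` (the winning candidate) and `scores` (data
#'   frame locus_tag, rf, external_branch; empty for a single candidate).
#' @export
select_copy <- function(candidates, cohort, species_tree, model = "poisson") {
  if (!length(candidates)) stop("no candidates")
  if (length(candidates) == 1) {
    return(list(selected = candidates[[1]],
                scores = data.frame(locus_tag = character(), rf = integer(),
                                    external_branch = numeric())))
  }
  scores <- lapply(candidates, score_candidate, cohort = cohort,
                   species_tree = species_tree, model = model)
  tab <- data.frame(
    locus_tag = vapply(scores, `[[`, character(1), "locus_tag"),
    rf = vapply(scores, `[[`, numeric(1), "rf"),
    external_branch = vapply(scores, `[[`, numeric(1), "external_branch"),
    stringsAsFactors = FALSE)
  pick <- order(tab$rf, tab$external_branch, tab$locus_tag)[1]
  list(selected = candidates[[pick]], scores = tab)
}

#' Assign nif1/nif2 identities to dual operon sets
#'
#' For each genome carrying two nif operon sets and each shared gene tree, the
#' set whose tip lies at the smaller patristic distance to the reference
#' genome's nif1 tip votes "nif1" (the other "nif2"); the per-genome label is
#' the majority across genes, with the vote margin reported. Tips of dual
#' genomes are expected to be labelled `<genome>` and `<genome>__set2` in the
#' gene trees (the reference genome included). Genomes with a single set are
#' labelled nif1 (vertical presumption).
#'
#' @param dual_genomes character vector of genomes with two sets.
#' @param reference_genome the genome whose sets carry known labels.
#' @param reference_labels named character vector mapping the reference's
#'   bookkeeping sets to identities, e.g. `c(set1 = "nif1", set2 = "nif2")`.
#' @param gene_trees named list of `phylo` gene trees.
#' @param single_genomes genomes with one set, labelled nif1 by default.
#' @return data frame: genome_id, set_label, identity, votes_nif1, votes_nif2,
#'   margin.
#' @export
assign_set_identity <- function(dual_genomes, reference_genome,
                                reference_labels = c(set1 = "nif1", set2 = "nif2"),
                                gene_trees, single_genomes = character()) {
  stopifnot(all(sort(unname(reference_labels)) == c("nif1", "nif2")))
  ref_set1_is_nif1 <- reference_labels[["set1"]] == "nif1"
  rows <- list()
  for (g in setdiff(dual_genomes, reference_genome)) {
    votes <- c(set1_nif1 = 0L, set1_nif2 = 0L)
    used <- 0L
    for (gt in gene_trees) {
      tips <- gt$tip.label
      need <- c(g, paste0(g, "__set2"), reference_genome)
      if (!all(need %in% tips)) next   # reference or a set absent: abstain
      pd <- ape::cophenetic.phylo(gt)
      ref_nif1_tip <- if (ref_set1_is_nif1) reference_genome else
        paste0(reference_genome, "__set2")
      if (!(ref_nif1_tip %in% tips)) next
      d1 <- pd[g, ref_nif1_tip]
      d2 <- pd[paste0(g, "__set2"), ref_nif1_tip]
      if (d1 < d2) votes["set1_nif1"] <- votes["set1_nif1"] + 1L
      else if (d2 < d1) votes["set1_nif2"] <- votes["set1_nif2"] + 1L
      used <- used + 1L
    }
    if (used == 0L) stop("all genes abstained for genome ", g,
                         " (reference absent from every gene tree)")
    set1_id <- if (votes["set1_nif1"] >= votes["set1_nif2"]) "nif1" else "nif2"
    set2_id <- setdiff(c("nif1", "nif2"), set1_id)
    margin <- abs(votes["set1_nif1"] - votes["set1_nif2"])
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = g, set_label = c("set1", "set2"),
      identity = c(set1_id, set2_id),
      votes_nif1 = unname(votes["set1_nif1"]),
      votes_nif2 = unname(votes["set1_nif2"]),
      margin = unname(margin), stringsAsFactors = FALSE)
  }
  if (reference_genome %in% dual_genomes) {
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = reference_genome, set_label = c("set1", "set2"),
      identity = unname(reference_labels[c("set1", "set2")]),
      votes_nif1 = NA_integer_, votes_nif2 = NA_integer_, margin = NA_integer_,
      stringsAsFactors = FALSE)
  }
  for (g in single_genomes) {
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = g, set_label = "set1", identity = "nif1",
      votes_nif1 = NA_integer_, votes_nif2 = NA_integer_, margin = NA_integer_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$genome_id, out$set_label), , drop = FALSE]
}
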