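#' Run the full nif history inference pipeline
#'
#' End-to-end chain on a dataset (in-memory [simulate_scenario()] output or a
#' [read_dataset()] result): tag nif candidates from orthogroups, call operons
#' and dual sets per genome, obtain a rooted species tree (estimated from the
#' concatenated markers by neighbor joining and rooted on the outgroup, or
#' supplied), build per-gene NJ trees from the proteome sequences of the
#' called loci (paralogs resolved by [select_copy()]), classify each carrier's
#' history per gene, assign nif1/nif2 identities to dual sets, reconstruct
#' Dollo loss histories per template and for the whole repertoire, and test
#' the monophyly of species-tree groups on every gene tree.
#'
#' The pipeline contains no random step: identical inputs give byte-identical
#' reports.
#'
#' @param dataset list with `annotations`, `proteomes`, `orthogroups`,
#'   `markers` (and optionally `species_tree`).
#' @param config a [nif_config()].
#' @param species_tree optional rooted ingroup `phylo` to use instead of the
#'   marker-estimated tree.
#' @param outgroup tip label used to root the estimated species tree.
#' @param reference_genome,reference_labels reference for nif1/nif2 set
#'   identity (see [assign_set_identity()]); defaults to the alphabetically
#'   first dual genome with `set1 = nif1`.
#' @param n_groups number of named taxon groups carved from the species tree
#'   for per-gene monophyly assessment.
#' @param k,incongruence_margin thresholds of [classify_gene_history()].
#' @return list of class `nif_pipeline_result`: `report` (a
#'   [summarize_history()] report), `calls`, `call_table`, `species_tree`,
#'   `gene_trees`, `classifications`, `groups`, `monophyly`, `paralog_scores`.
#' @export
run_nif_pipeline <- function(dataset, config = nif_config(),
                             species_tree = NULL, outgroup = "Outgroup",
                             reference_genome = NULL,
                             reference_labels = c(set1 = "nif1", set2 = "nif2"),
                             n_groups = 5, k = 3, incongruence_margin = 2) {
  catalog <- map_nif_orthogroups(dataset$annotations, dataset$orthogroups)
  tagged <- lapply(dataset$annotations, tag_nif_candidates,
                   orthogroups = dataset$orthogroups, catalog = catalog,
                   config = config)
  calls_by_genome <- lapply(tagged, call_operons, config = config,
                            catalog = catalog)
  calls <- unlist(unname(calls_by_genome), recursive = FALSE)
  dual_genomes <- names(calls_by_genome)[vapply(calls_by_genome,
                                                function(x) isTRUE(attr(x, "dual_set")),
                                                logical(1))]
  # species tree
  if (is.null(species_tree)) {
    concat <- concatenate_alignments(dataset$markers)
    nj <- neighbor_joining(protein_distance(concat))
    rooted <- root_at_outgroup(nj, outgroup)
    species_tree <- ape::drop.tip(rooted, outgroup)
  }
  species_tree <- ape::reorder.phylo(species_tree, "cladewise")

  # per-gene alignments from called loci (+ residual singletons)
  templates <- operon_templates()
  genes <- catalog$gene_names
  gene_aln <- stats::setNames(vector("list", length(genes)), genes)
  paralog_scores <- list()
  loci <- .collect_gene_loci(tagged, calls_by_genome, catalog)
  for (g in genes) {
    rows <- loci[loci$gene == g, , drop = FALSE]
    if (!nrow(rows)) next
    aln <- character(0)
    # fused loci contribute a substring; component length taken from the
    # unfused majority
    comp_len <- .component_length(rows, dataset$proteomes, g, catalog)
    for (tipname in unique(rows$tip)) {
      sub <- rows[rows$tip == tipname, , drop = FALSE]
      seqs <- vapply(seq_len(nrow(sub)), function(i) {
        s <- dataset$proteomes[[sub$genome_id[i]]][[sub$locus_tag[i]]]
        if (sub$fused[i]) .fused_component(s, g, comp_len, catalog) else s
      }, character(1))
      if (length(seqs) > 1) {
        pickres <- .resolve_paralogs(g, tipname, sub, seqs, gene_aln, loci,
                                     dataset, species_tree)
        paralog_scores[[paste(g, tipname)]] <- pickres$scores
        seqs <- pickres$seq
      }
      aln[tipname] <- seqs[1]
    }
    if (length(unique(nchar(aln))) == 1 && length(aln) >= 3) {
      gene_aln[[g]] <- aln
    }
  }
  gene_trees <- lapply(gene_aln, function(aln) {
    if (is.null(aln) || length(aln) < 4) return(NULL)
    neighbor_joining(protein_distance(aln))
  })

  # classification per gene x carrier (plain tips only); gene trees rooted on
  # the species tree's earliest-diverging carrier clade
  root_taxa <- basal_clade(species_tree)
  classifications <- list()
  for (g in genes) {
    gt <- gene_trees[[g]]
    if (is.null(gt)) next
    rooted <- root_gene_tree(gt, root_taxa)
    outl <- gene_tree_outliers(rooted, k = k)
    plain <- grep("__set2$", gt$tip.label, invert = TRUE, value = TRUE)
    sp_outl <- species_tree_outliers(species_tree, plain, k = k)
    for (tax in plain) {
      classifications[[paste(g, tax)]] <-
        classify_gene_history(tax, g, rooted, species_tree, outliers = outl,
                              k = k, incongruence_margin = incongruence_margin,
                              species_outliers = sp_outl)
    }
  }

  # diazotroph verdicts and loss histories
  genomes <- names(dataset$annotations)
  diaz <- stats::setNames(vapply(genomes, function(gn) {
    all(vapply(names(templates), function(tn)
      gn %in% presence_profile(calls_by_genome[[gn]], tn), logical(1)))
  }, logical(1)), genomes)
  histories <- list()
  for (tn in names(templates)) {
    present <- presence_profile(calls, tn)
    histories[[tn]] <- if (length(present))
      dollo_reconstruct(species_tree, present) else NULL
  }
  histories[["diazotroph"]] <- if (any(diaz))
    dollo_reconstruct(species_tree, names(diaz)[diaz]) else NULL

  # non-diazotroph homolog carriers (Table-1 analogue)
  carrier_rows <- list()
  for (gn in genomes[!diaz]) {
    hits <- loci[loci$genome_id == gn, , drop = FALSE]
    for (g in unique(hits$gene)) {
      carrier_rows[[length(carrier_rows) + 1L]] <-
        data.frame(genome_id = gn, gene = g, stringsAsFactors = FALSE)
    }
  }
  carriers <- if (length(carrier_rows)) do.call(rbind, carrier_rows) else
    data.frame(genome_id = character(), gene = character())

  # dual set identity
  set_identity <- NULL
  if (length(dual_genomes)) {
    if (is.null(reference_genome)) reference_genome <- sort(dual_genomes)[1]
    set_identity <- tryCatch(
      assign_set_identity(dual_genomes, reference_genome, reference_labels,
                          Filter(Negate(is.null), gene_trees),
                          single_genomes = setdiff(names(diaz)[diaz], dual_genomes)),
      error = function(e) NULL)
  }

  # group definitions and per-gene monophyly
  groups <- define_groups(species_tree, diaz, n_groups = n_groups)
  monophyly <- .group_monophyly(gene_trees, groups, root_taxa)

  report <- summarize_history(unname(classifications), histories, diaz,
                              carriers = carriers, set_identity = set_identity)
  structure(list(report = report, calls = calls,
                 call_table = operon_call_table(calls),
                 species_tree = species_tree, gene_trees = gene_trees,
                 classifications = classifications, groups = groups,
                 monophyly = monophyly, paralog_scores = paralog_scores,
                 diazotroph = diaz, histories = histories),
            class = "nif_pipeline_result")
}

#' @export
print.nif_pipeline_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

# all nif loci visible to the pipeline: operon-call members plus tagged
# singletons; tip = genome id, with "__set2" suffix for set2 call members
.collect_gene_loci <- function(tagged, calls_by_genome, catalog) {
  rows <- list()
  for (gn in names(tagged)) {
    seen <- character(0)
    for (cl in calls_by_genome[[gn]]) {
      suffix <- if (identical(cl$set_label, "set2")) "__set2" else ""
      for (i in seq_len(nrow(cl$members))) {
        lab <- cl$members$nif_gene[i]
        for (g in nif_components(lab, catalog)[[1]]) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene = g, genome_id = gn, locus_tag = cl$members$locus_tag[i],
            tip = paste0(gn, suffix), fused = lab %in% names(catalog$fused_names),
            source = "operon_call", stringsAsFactors = FALSE)
        }
        seen <- c(seen, cl$members$locus_tag[i])
      }
    }
    ann <- tagged[[gn]]
    extra <- which(!is.na(ann$nif_gene) & !(ann$locus_tag %in% seen))
    for (i in extra) {
      for (g in nif_components(ann$nif_gene[i], catalog)[[1]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, genome_id = gn, locus_tag = ann$locus_tag[i],
          tip = gn, fused = ann$nif_gene[i] %in% names(catalog$fused_names),
          source = "ortholog_hit", stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = character(), genome_id = character(),
                      locus_tag = character(), tip = character(),
                      fused = logical(), source = character()))
  }
  unique(do.call(rbind, rows))
}

# length of component `g` inside fused proteins: modal length among unfused loci
.component_length <- function(rows, proteomes, g, catalog) {
  plain <- rows[!rows$fused, , drop = FALSE]
  if (!nrow(plain)) return(NA_integer_)
  lens <- vapply(seq_len(nrow(plain)), function(i)
    nchar(proteomes[[plain$genome_id[i]]][[plain$locus_tag[i]]]), integer(1))
  as.integer(names(sort(table(lens), decreasing = TRUE))[1])
}

.fused_component <- function(seq, g, comp_len, catalog) {
  comp <- catalog$fused_names[["nifEN"]]
  if (is.na(comp_len)) return(seq)
  if (g == comp[1]) substr(seq, 1, comp_len)
  else substr(seq, nchar(seq) - comp_len + 1L, nchar(seq))
}

# choose among same-tip paralog sequences by species-tree congruence, using
# the single-copy carriers of the same gene as the cohort
.resolve_paralogs <- function(g, tipname, sub, seqs, gene_aln, loci, dataset,
                              species_tree) {
  genome <- sub$genome_id[1]
  others <- loci[loci$gene == g & loci$genome_id != genome &
                   !grepl("__set2$", loci$tip), , drop = FALSE]
  single <- names(which(table(others$genome_id) == 1))
  cohort <- character(0)
  for (gn in single) {
    r <- others[others$genome_id == gn, ][1, ]
    s <- dataset$proteomes[[gn]][[r$locus_tag]]
    if (r$fused) s <- .fused_component(s, g, .component_length(
      others, dataset$proteomes, g, dataset$catalog %||% nif_catalog()), nif_catalog())
    cohort[gn] <- s
  }
  cohort <- cohort[nchar(cohort) == nchar(seqs[1])]
  cohort <- cohort[names(cohort) %in% species_tree$tip.label]
  if (length(cohort) < 3 || !(genome %in% species_tree$tip.label)) {
    pick <- order(sub$locus_tag)[1]
    return(list(seq = seqs[pick], scores = NULL))
  }
  candidates <- lapply(seq_len(nrow(sub)), function(i)
    list(gene_name = g, genome_id = genome, locus_tag = sub$locus_tag[i],
         sequence = seqs[i]))
  sel <- select_copy(candidates, cohort, species_tree)
  list(seq = sel$selected$sequence, scores = sel$scores)
}

#' Carve named taxon groups out of a species tree
#'
#' Picks the `n_groups` largest disjoint clades of the rooted species tree
#' whose leaves are all diazotrophs (at least two leaves each), named
#' "group I", "group II", ... in order of size. The analogue of dividing the
#' diazotrophic taxa into monophyletic reference groups for tree comparison;
#' taxa with no groupable relatives stay ungrouped.
#'
#' @param species_tree rooted `phylo`.
#' @param diazotroph named logical vector over the tree's tips.
#' @param n_groups maximum number of groups.
#' @return named list of character vectors (possibly fewer than `n_groups`).
#' @export
define_groups <- function(species_tree, diazotroph, n_groups = 5) {
  nt <- length(species_tree$tip.label)
  sets <- .node_tip_sets(species_tree)
  cand <- which(vapply(seq_along(sets), function(x)
    x > nt && all(diazotroph[sets[[x]]]) && length(sets[[x]]) >= 2 &&
      length(sets[[x]]) < sum(diazotroph), logical(1)))
  cand <- cand[order(-lengths(sets[cand]))]
  chosen <- list()
  used <- character(0)
  for (x in cand) {
    if (length(chosen) >= n_groups) break
    if (!length(intersect(sets[[x]], used))) {
      chosen[[length(chosen) + 1L]] <- sets[[x]]
      used <- c(used, sets[[x]])
    }
  }
  if (length(chosen)) {
    names(chosen) <- paste("group", utils::as.roman(seq_along(chosen)))
  }
  chosen
}

.group_monophyly <- function(gene_trees, groups, root_taxa = NULL) {
  out <- list()
  for (g in names(gene_trees)) {
    gt <- gene_trees[[g]]
    if (is.null(gt)) next
    rooted <- root_gene_tree(gt, root_taxa)
    for (grp in names(groups)) {
      taxa <- intersect(groups[[grp]], rooted$tip.label)
      if (length(taxa) < 2) next
      v <- is_monophyletic(rooted, taxa)
      out[[length(out) + 1L]] <- data.frame(
        gene = g, group = grp, monophyletic = v$monophyletic,
        n_intruders = length(v$intruders), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(gene = character(), group = character(),
                                      monophyletic = logical(),
                                      n_intruders = integer()))
  do.call(rbind, out)
}
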