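#' @title Operon detection from ordered gene tables
#' @description
#' The detection chain is: [cluster_nif_loci()] merges nif-tagged genes into
#' clusters by the intergenic gap rule; [bridge_orphans()] rescues isolated nif
#' genes flanked by operons on both sides; [split_and_match()] assigns cluster
#' members to the four canonical operon templates (splitting super-operons);
#' [detect_dual_operon_sets()] recognises genomes carrying two operon sets at
#' distant genomic positions. [call_operons()] runs the whole chain.
#' @name operon_detection
NULL

.nif_rows <- function(annotation, config) {
  ok <- !is.na(annotation$nif_gene) & !annotation$pseudo
  if (!config$include_unconfirmed) {
    ok <- ok & (is.na(annotation$nif_evidence) |
                  annotation$nif_evidence != "unconfirmed")
  }
  annotation[ok, , drop = FALSE]
}

.new_cluster <- function(members, genome_id, contig_id) {
  members <- members[order(members$ordinal), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(genome_id = genome_id, contig_id = contig_id,
                 members = members,
                 span = range(members$ordinal),
                 intervening_counts = if (nrow(members) > 1)
                   diff(members$ordinal) - 1L else integer(0)),
            class = "nif_cluster")
}

#' Cluster nif genes by the intergenic gap rule
#'
#' Within each contig, consecutive nif-tagged genes are merged into one cluster
#' whenever strictly fewer than `config$max_gap` annotated genes (of any kind)
#' lie strictly between them, i.e. their ordinal difference minus one is less
#' than `max_gap`. Clusters never span contigs; every nif gene lands in exactly
#' one cluster (possibly a singleton).
#'
#' @param annotation a gene table that has been through [tag_nif_candidates()].
#' @param config a [nif_config()].
#' @return list of `nif_cluster` objects, each with the genome and contig id,
#'   a `members` gene-table slice (with a `bridged` flag column), the ordinal
#'   `span`, and `intervening_counts` between consecutive members.
#' @export
cluster_nif_loci <- function(annotation, config = nif_config()) {
  nif <- .nif_rows(annotation, config)
  if (!nrow(nif)) return(list())
  nif$bridged <- FALSE
  clusters <- list()
  for (ct in unique(nif$contig_id)) {
    rows <- nif[nif$contig_id == ct, , drop = FALSE]
    rows <- rows[order(rows$ordinal), , drop = FALSE]
    brk <- if (nrow(rows) > 1) {
      gap_break <- (diff(rows$ordinal) - 1L) >= config$max_gap
      if (config$respect_strand) {
        gap_break | (rows$strand[-nrow(rows)] != rows$strand[-1])
      } else gap_break
    } else logical(0)
    grp <- cumsum(c(0L, as.integer(brk)))
    for (g in unique(grp)) {
      clusters[[length(clusters) + 1L]] <-
        .new_cluster(rows[grp == g, , drop = FALSE],
                     unique(rows$genome_id), ct)
    }
  }
  clusters
}

#' Bridge isolated nif genes flanked by nif operons
#'
#' A singleton nif cluster whose nearest nif clusters upstream AND downstream
#' on the same contig are both multi-gene clusters is merged with both; the
#' formerly isolated member is flagged `bridged`. Applied iteratively to a
#' fixed point. A no-op when `config$bridging_enabled` is off.
#'
#' @param clusters output of [cluster_nif_loci()].
#' @param annotation the same gene table (kept for interface symmetry).
#' @param config a [nif_config()].
#' @return list of `nif_cluster` objects.
#' @export
bridge_orphans <- function(clusters, annotation = NULL, config = nif_config()) {
  if (!config$bridging_enabled || length(clusters) < 3) return(clusters)
  repeat {
    key <- vapply(clusters, function(cl)
      paste(cl$genome_id, cl$contig_id, sep = "\r"), character(1))
    merged_any <- FALSE
    out <- list()
    for (kc in unique(key)) {
      idx <- which(key == kc)
      idx <- idx[order(vapply(clusters[idx], function(cl) cl$span[1], numeric(1)))]
      sizes <- vapply(clusters[idx], function(cl) nrow(cl$members), integer(1))
      i <- 2L
      consumed <- rep(FALSE, length(idx))
      while (i <= length(idx) - 1L) {
        if (!consumed[i - 1L] && sizes[i] == 1L &&
            sizes[i - 1L] > 1L && sizes[i + 1L] > 1L) {
          a <- clusters[[idx[i - 1L]]]; b <- clusters[[idx[i]]]
          c_ <- clusters[[idx[i + 1L]]]
          b$members$bridged <- TRUE
          m <- rbind(a$members, b$members, c_$members)
          merged <- .new_cluster(m, a$genome_id, a$contig_id)
          clusters[[idx[i - 1L]]] <- merged
          consumed[i] <- consumed[i + 1L] <- TRUE
          sizes[i - 1L] <- nrow(merged$members)
          merged_any <- TRUE
          i <- i + 2L
        } else i <- i + 1L
      }
      out <- c(out, clusters[idx[!consumed]])
    }
    clusters <- out
    if (!merged_any) break
  }
  clusters
}

#' Split a cluster into canonical operon calls
#'
#' Cluster members are assigned to the operon templates by nif label; a fused
#' nifEN record satisfies both nifE and nifN of nifENXW. A super-operon cluster
#' containing members of several templates yields one call per represented
#' template. A nifK lying in a cluster with nifENXW members but no nifH/nifD is
#' reported as part of the nifENXW call (cross-reference flag) rather than as a
#' fabricated nifHDK call. Labels not in any template are attached as extras of
#' the nearest call (by ordinal distance).
#'
#' @param cluster a `nif_cluster`.
#' @param templates named list of templates, see [operon_templates()].
#' @param catalog a [nif_catalog()].
#' @return list of `operon_call` objects: template name, genome/contig ids,
#'   `members` slice, status ("complete" iff no template member missing, else
#'   "partial"; [detect_dual_operon_sets()] may later mark "split"), `missing`,
#'   `extras`, `insertions` (non-nif genes interior to the call span),
#'   `set_label`, and flags.
#' @export
split_and_match <- function(cluster, templates = operon_templates(),
                            catalog = nif_catalog()) {
  m <- cluster$members
  comps <- nif_components(m$nif_gene, catalog)
  gene2template <- unlist(lapply(names(templates), function(tn)
    stats::setNames(rep(tn, length(templates[[tn]])), templates[[tn]])))
  member_templates <- lapply(comps, function(cc)
    unique(unname(gene2template[cc[cc %in% names(gene2template)]])))
  if (!any(lengths(member_templates) > 0)) {
    warning("cluster has no template-member labels")
    return(list())
  }
  present_templates <- unique(unlist(member_templates))
  # nifK cross-reference: nifK present with nifENXW members but nifH/nifD absent
  labels_flat <- unlist(comps)
  nifk_cross <- "nifK" %in% labels_flat &&
    !any(c("nifH", "nifD") %in% labels_flat) &&
    any(c("nifE", "nifN", "nifX", "nifW") %in% labels_flat) &&
    "nifENXW" %in% names(templates)
  calls <- list()
  for (tn in present_templates) {
    take <- vapply(member_templates, function(tt) tn %in% tt, logical(1))
    if (tn == "nifHDK" && nifk_cross) {
      take <- take & vapply(comps, function(cc) !identical(cc, "nifK"), logical(1))
      if (!any(take)) next
    }
    extras_take <- rep(FALSE, nrow(m))
    if (tn == "nifENXW" && nifk_cross) {
      extras_take <- vapply(comps, function(cc) identical(cc, "nifK"), logical(1))
    }
    sel <- m[take | extras_take, , drop = FALSE]
    present <- intersect(templates[[tn]], unlist(comps[take]))
    missing <- setdiff(templates[[tn]], present)
    span <- range(sel$ordinal)
    n_nif_in_span <- sum(cluster$members$ordinal >= span[1] &
                           cluster$members$ordinal <= span[2])
    calls[[length(calls) + 1L]] <- structure(list(
      template = tn, genome_id = cluster$genome_id,
      contig_id = cluster$contig_id,
      members = sel[order(sel$ordinal), , drop = FALSE],
      status = if (!length(missing)) "complete" else "partial",
      missing = missing,
      extras = setdiff(unique(unlist(comps[extras_take])), character(0)),
      insertions = as.integer(diff(span) + 1L - n_nif_in_span),
      set_label = NA_character_,
      supernumerary = FALSE,
      nifk_crossref = tn == "nifENXW" && nifk_cross),
      class = "operon_call")
  }
  # labels in the catalog but in no template: extras of the nearest call
  orphan <- which(lengths(member_templates) == 0 & !is.na(m$nif_gene))
  for (i in orphan) {
    d <- vapply(calls, function(cl)
      min(abs(cl$members$ordinal - m$ordinal[i])), numeric(1))
    j <- which.min(d)
    calls[[j]]$extras <- union(calls[[j]]$extras, m$nif_gene[i])
  }
  calls
}

#' Detect dual nif operon sets in a genome
#'
#' If two calls share a template and are separated by at least
#' `config$dual_set_min_separation` genes (or lie on different contigs), the
#' genome carries two nif operon sets. Calls are partitioned into co-location
#' groups (single linkage: calls within the separation threshold on one contig
#' share a group); the two largest groups become set1 and set2 (ordered by
#' genomic position). Same-template fragments within one group are marked
#' status "split". Three or more same-template calls beyond the two sets are
#' flagged "supernumerary".
#'
#' @param calls list of `operon_call` for ONE genome.
#' @param config a [nif_config()].
#' @return the calls with `set_label` (and possibly status/flags) updated, plus
#'   attribute `dual_set` (logical).
#' @export
detect_dual_operon_sets <- function(calls, config = nif_config()) {
  if (!length(calls)) return(structure(calls, dual_set = FALSE))
  n <- length(calls)
  lo <- vapply(calls, function(cl) min(cl$members$ordinal), numeric(1))
  hi <- vapply(calls, function(cl) max(cl$members$ordinal), numeric(1))
  contig <- vapply(calls, function(cl) cl$contig_id, character(1))
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i >= j || grp[i] == grp[j]) next
      gap <- max(lo[i], lo[j]) - min(hi[i], hi[j]) - 1
      if (contig[i] == contig[j] && gap < config$dual_set_min_separation) {
        grp[grp == grp[j]] <- grp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  groups <- split(seq_len(n), grp)
  tmpl <- vapply(calls, function(cl) cl$template, character(1))
  group_of <- match(grp, names(groups))
  dual <- any(vapply(unique(tmpl), function(tn)
    length(unique(group_of[tmpl == tn])) > 1, logical(1)))
  # mark co-located same-template fragments as split
  for (g in groups) {
    for (tn in unique(tmpl[g])) {
      idx <- g[tmpl[g] == tn]
      if (length(idx) > 1) for (i in idx) calls[[i]]$status <- "split"
    }
  }
  if (dual) {
    size <- vapply(groups, function(g) length(unique(tmpl[g])), integer(1))
    pos <- vapply(groups, function(g) min(lo[g]), numeric(1))
    gcontig <- vapply(groups, function(g) contig[g[1]], character(1))
    top2 <- order(-size, gcontig, pos)[seq_len(min(2, length(groups)))]
    top2 <- top2[order(gcontig[top2], pos[top2])]
    for (i in groups[[top2[1]]]) calls[[i]]$set_label <- "set1"
    if (length(top2) > 1) for (i in groups[[top2[2]]]) calls[[i]]$set_label <- "set2"
    leftover <- setdiff(seq_len(n), unlist(groups[top2]))
    for (i in leftover) {
      if (sum(tmpl == tmpl[i]) > 2) calls[[i]]$supernumerary <- TRUE
    }
  } else {
    for (i in seq_len(n)) calls[[i]]$set_label <- "set1"
  }
  structure(calls, dual_set = dual)
}

#' Run the full operon-detection chain on one genome
#'
#' @param annotation a tagged gene table (see [tag_nif_candidates()]).
#' @param config a [nif_config()].
#' @param templates see [operon_templates()].
#' @param catalog see [nif_catalog()].
#' @return list of `operon_call` with attribute `dual_set`.
#' @export
call_operons <- function(annotation, config = nif_config(),
                         templates = operon_templates(),
                         catalog = nif_catalog()) {
  clusters <- cluster_nif_loci(annotation, config)
  clusters <- bridge_orphans(clusters, annotation, config)
  calls <- list()
  for (cl in clusters) {
    calls <- c(calls, suppressWarnings(split_and_match(cl, templates, catalog)))
  }
  detect_dual_operon_sets(calls, config)
}

#' Tabulate operon calls
#'
#' @param calls list of `operon_call` (possibly across genomes).
#' @return data frame with one row per call: genome, contig, template, status,
#'   members (label:ordinal, comma-separated), missing, extras, insertions,
#'   set_label and flags.
#' @export
operon_call_table <- function(calls) {
  if (!length(calls)) {
    return(data.frame(genome_id = character(), contig_id = character(),
                      template = character(), status = character(),
                      members = character(), missing = character(),
                      extras = character(), insertions = integer(),
                      set_label = character(), supernumerary = logical(),
                      nifk_crossref = logical(), n_bridged = integer()))
  }
  do.call(rbind, lapply(calls, function(cl) {
    data.frame(
      genome_id = cl$genome_id, contig_id = cl$contig_id,
      template = cl$template, status = cl$status,
      members = paste(sprintf("%s:%d", cl$members$nif_gene,
                              cl$members$ordinal), collapse = ","),
      missing = paste(cl$missing, collapse = ","),
      extras = paste(cl$extras, collapse = ","),
      insertions = cl$insertions,
      set_label = cl$set_label,
      supernumerary = cl$supernumerary,
      nifk_crossref = cl$nifk_crossref,
      n_bridged = sum(cl$members$bridged %in% TRUE),
      stringsAsFactors = FALSE)
  }))
}

#' @export
print.operon_call <- function(x, ...) {
  cat(sprintf("<operon_call> %s %s [%s] %s: %s\n", x$genome_id, x$contig_id,
              x$template, x$status,
              paste(x$members$nif_gene, collapse = " ")))
  if (length(x$missing)) cat("  missing:", paste(x$missing, collapse = " "), "\n")
  invisible(x)
}
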