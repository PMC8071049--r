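#' Canonical catalog of nif genes
#'
#' The molybdenum-dependent nitrogenase system of Cyanobacteria is encoded by
#' thirteen nif genes organised in four operons (see [operon_templates()]).
#' The catalog records the canonical gene names, known gene fusions (nifE and
#' nifN occur as a single fused nifEN coding sequence in several genomes), and
#' an optional mapping from orthogroup identifiers to canonical names used by
#' [tag_nif_candidates()].
#'
#' @param orthogroup_map named character vector mapping orthogroup ids to
#'   canonical nif names (a fused name such as `"nifEN"` is allowed).
#' @return an object of class `nif_catalog`: a list with elements `gene_names`,
#'   `fused_names` (named list mapping fused name to its two components) and
#'   `orthogroup_map`.
#' @export
nif_catalog <- function(orthogroup_map = character()) {
  genes <- c("nifB", "nifS", "nifU", "nifH", "nifD", "nifK",
             "nifE", "nifN", "nifX", "nifW", "nifV", "nifZ", "nifT")
  fused <- list(nifEN = c("nifE", "nifN"))
  if (length(orthogroup_map)) {
    bad <- setdiff(unname(orthogroup_map), c(genes, names(fused)))
    if (length(bad)) {
      stop("orthogroup_map contains names outside the nif catalog: ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(gene_names = genes, fused_names = fused,
                 orthogroup_map = orthogroup_map),
            class = "nif_catalog")
}

#' Expand a nif label into its component gene names
#'
#' A fused label (e.g. `"nifEN"`) counts as both of its components for all
#' operon template logic; plain labels map to themselves.
#'
#' @param label character vector of nif labels.
#' @param catalog a [nif_catalog()].
#' @return list (one element per label) of component gene names.
#' @export
nif_components <- function(label, catalog = nif_catalog()) {
  lapply(label, function(l) {
    if (is.na(l)) return(character())
    if (l %in% names(catalog$fused_names)) catalog$fused_names[[l]] else l
  })
}

#' Canonical nif operon templates
#'
#' The four nif operons conserved across diazotrophic Cyanobacteria.
#'
#' @return named list of character vectors of member gene names, in canonical
#'   gene order.
#' @export
operon_templates <- function() {
  list(nifBSU  = c("nifB", "nifS", "nifU"),
       nifHDK  = c("nifH", "nifD", "nifK"),
       nifENXW = c("nifE", "nifN", "nifX", "nifW"),
       nifVZT  = c("nifV", "nifZ", "nifT"))
}

#' Configuration of the operon-detection rules
#'
#' @param max_gap two nif genes are merged into one cluster when strictly fewer
#'   than `max_gap` annotated genes (of any kind) lie strictly between them.
#'   Default 4, i.e. the "< 4 intervening genes" rule.
#' @param bridging_enabled if `TRUE`, an isolated nif gene flanked on both
#'   sides (same contig) by multi-gene nif clusters is merged with them even
#'   though the gap rule fails; bridged members are flagged in output.
#' @param dual_set_min_separation two same-template operon calls separated by
#'   at least this many genes (or on different contigs) indicate a duplicated
#'   ("dual") nif operon set.
#' @param respect_strand if `TRUE`, genes on opposite strands are never merged
#'   into one cluster. Off by default: the gap rule counts genes only.
#' @param include_unconfirmed if `TRUE`, records whose annotation says "nif*"
#'   but that lack orthogroup support are still used in operon detection.
#' @return a list of class `nif_config`.
#' @export
nif_config <- function(max_gap = 4, bridging_enabled = TRUE,
                       dual_set_min_separation = 50, respect_strand = FALSE,
                       include_unconfirmed = FALSE) {
  stopifnot(max_gap >= 1, dual_set_min_separation >= 1)
  structure(list(max_gap = as.integer(max_gap),
                 bridging_enabled = isTRUE(bridging_enabled),
                 dual_set_min_separation = as.integer(dual_set_min_separation),
                 respect_strand = isTRUE(respect_strand),
                 include_unconfirmed = isTRUE(include_unconfirmed)),
            class = "nif_config")
}
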