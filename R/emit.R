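#' Write a simulated dataset to disk
#'
#' Emits per-genome gene-table TSVs, per-genome protein FASTAs, the orthogroup
#' TSV, per-marker aligned FASTAs, the true species tree (Newick) and a truth
#' JSON. All files are plain text and parse cleanly with the package readers;
#' emission is byte-deterministic for a given dataset.
#'
#' @param dataset a [simulate_scenario()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
emit_dataset <- function(dataset, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  for (d in c("genomes", "proteomes", "markers")) {
    dir.create(file.path(dir, d), showWarnings = FALSE)
  }
  for (g in names(dataset$annotations)) {
    write_gene_table(dataset$annotations[[g]],
                     file.path(dir, "genomes", paste0(g, ".tsv")))
    write_alignment_fasta(dataset$proteomes[[g]],
                          file.path(dir, "proteomes", paste0(g, ".faa")))
  }
  write_orthogroup_table(dataset$orthogroups, file.path(dir, "orthogroups.tsv"))
  for (m in names(dataset$markers)) {
    write_alignment_fasta(dataset$markers[[m]],
                          file.path(dir, "markers", paste0(m, ".faa")))
  }
  ape::write.tree(dataset$species_tree, file.path(dir, "species_tree.nwk"))
  truth <- dataset$truth
  truth_json <- list(
    diazotroph = as.list(truth$diazotroph),
    canonical_gain = truth$canonical_gain,
    canonical_losses = truth$canonical_losses,
    n_canonical_losses = truth$n_canonical_losses,
    residuals = as.list(truth$residuals),
    dual = truth$dual[c("recipient_leaves", "donor", "reference_genome")],
    hgt = truth$hgt,
    fused = as.list(truth$fused))
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Read an emitted dataset back from disk
#'
#' @param dir a directory written by [emit_dataset()].
#' @return list with `annotations`, `proteomes`, `orthogroups`, `markers`,
#'   `species_tree` (the truth JSON is left on disk; analysis code must not
#'   read it).
#' @export
read_dataset <- function(dir) {
  gfiles <- sort(list.files(file.path(dir, "genomes"), "\\.tsv$",
                            full.names = TRUE))
  annotations <- lapply(gfiles, parse_gene_table)
  names(annotations) <- sub("\\.tsv$", "", basename(gfiles))
  pfiles <- sort(list.files(file.path(dir, "proteomes"), "\\.faa$",
                            full.names = TRUE))
  proteomes <- lapply(pfiles, read_alignment_fasta)
  names(proteomes) <- sub("\\.faa$", "", basename(pfiles))
  mfiles <- sort(list.files(file.path(dir, "markers"), "\\.faa$",
                            full.names = TRUE))
  markers <- lapply(mfiles, read_alignment_fasta)
  names(markers) <- sub("\\.faa$", "", basename(mfiles))
  list(annotations = annotations, proteomes = proteomes,
       orthogroups = read_orthogroup_table(file.path(dir, "orthogroups.tsv")),
       markers = markers,
       species_tree = ape::read.tree(file.path(dir, "species_tree.nwk")))
}
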