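#' Construct an orthogroup table
#'
#' An orthogroup table is a long-format data frame (orthogroup_id, genome_id,
#' protein_id). Each (genome_id, protein_id) pair belongs to at most one
#' orthogroup; groups are non-empty.
#'
#' @param df data frame with columns orthogroup_id, genome_id, protein_id.
#' @return data frame of class `orthogroup_table`.
#' @export
orthogroup_table <- function(df) {
  stopifnot(all(c("orthogroup_id", "genome_id", "protein_id") %in% names(df)))
  df <- as.data.frame(df)[, c("orthogroup_id", "genome_id", "protein_id")]
  key <- paste(df$genome_id, df$protein_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    clash <- df[key %in% key[dup], , drop = FALSE]
    multi <- unique(clash$protein_id[ave(as.integer(factor(clash$orthogroup_id)),
                                         paste(clash$genome_id, clash$protein_id),
                                         FUN = function(x) length(unique(x))) > 1])
    if (length(multi)) {
      stop("protein id in two orthogroups: ", paste(multi, collapse = ", "))
    }
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("orthogroup_table", "data.frame")
  df
}

#' Read an OrthoFinder-style orthogroup table
#'
#' Tab-separated: first column the orthogroup id, one column per genome,
#' cells holding comma-separated protein ids (empty cell = no members).
#'
#' @param path path to the TSV file.
#' @return an [orthogroup_table()].
#' @export
read_orthogroup_table <- function(path) {
  if (!file.exists(path)) stop("cannot read orthogroup table: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = NULL, colClasses = "character")
  if (ncol(df) < 2) stop("orthogroup table needs an id column plus genome columns")
  genomes <- names(df)[-1]
  rows <- list()
  for (i in seq_len(nrow(df))) {
    for (g in genomes) {
      cell <- df[i, g]
      if (is.na(cell) || !nzchar(trimws(cell))) next
      ids <- trimws(strsplit(cell, ",")[[1]])
      ids <- ids[nzchar(ids)]
      if (length(ids)) {
        rows[[length(rows) + 1L]] <- data.frame(
          orthogroup_id = df[i, 1], genome_id = g, protein_id = ids,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("orthogroup table has no memberships")
  orthogroup_table(do.call(rbind, rows))
}

#' Write an orthogroup table in the OrthoFinder dialect
#'
#' @param x an [orthogroup_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orthogroup_table <- function(x, path) {
  genomes <- sort(unique(x$genome_id))
  groups <- unique(x$orthogroup_id)
  wide <- data.frame(Orthogroup = groups, stringsAsFactors = FALSE)
  for (g in genomes) {
    wide[[g]] <- vapply(groups, function(og) {
      ids <- x$protein_id[x$orthogroup_id == og & x$genome_id == g]
      paste(sort(ids), collapse = ", ")
    }, character(1))
  }
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive the orthogroup-to-nif-name map from annotated genomes
#'
#' An orthogroup is mapped to a canonical nif name when the majority of its
#' member proteins carry that name (or a fused name) in the `gene_label`
#' column of the annotations. This reproduces the usual practice of seeding
#' nif candidate detection from "nif"-annotated proteins and extending it to
#' their whole orthogroup.
#'
#' @param annotations list of gene tables.
#' @param orthogroups an [orthogroup_table()].
#' @param catalog a [nif_catalog()].
#' @return the catalog with `orthogroup_map` populated.
#' @export
map_nif_orthogroups <- function(annotations, orthogroups, catalog = nif_catalog()) {
  labels <- do.call(rbind, lapply(annotations, function(a) {
    data.frame(genome_id = a$genome_id, protein_id = a$locus_tag,
               gene_label = a$gene_label, stringsAsFactors = FALSE)
  }))
  m <- merge(as.data.frame(orthogroups), labels,
             by = c("genome_id", "protein_id"), all.x = TRUE)
  valid <- c(catalog$gene_names, names(catalog$fused_names))
  m <- m[!is.na(m$gene_label) & m$gene_label %in% valid, , drop = FALSE]
  if (!nrow(m)) return(nif_catalog(character()))
  votes <- table(m$orthogroup_id, m$gene_label)
  map <- apply(votes, 1, function(v) colnames(votes)[which.max(v)])
  nif_catalog(orthogroup_map = map)
}

.kmer_counts <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(integer(0))
  kmers <- substring(seq, seq_len(n - k + 1L), k:n)
  table(kmers)
}

#' k-mer profile similarity of two protein sequences
#'
#' Cosine similarity of the k-mer count vectors of two sequences: 1 for
#' identical sequences, 0 for sequences sharing no k-mer. Symmetric and
#' invariant to scaling of the count vectors. A stand-in for all-vs-all
#' sequence search when building quick orthogroups; see
#' [build_orthogroups_rbh()].
#'
#' @param a,b protein sequences (single strings, amino-acid alphabet).
#' @param k k-mer size (default 4).
#' @return similarity in \[0, 1\].
#' @export
kmer_profile_similarity <- function(a, b, k = 4) {
  stopifnot(k >= 1)
  if (nchar(a) < k || nchar(b) < k) {
    warning("sequence shorter than k; similarity 0")
    return(0)
  }
  ca <- .kmer_counts(a, k)
  cb <- .kmer_counts(b, k)
  shared <- intersect(names(ca), names(cb))
  if (!length(shared)) return(0)
  num <- sum(as.numeric(ca[shared]) * as.numeric(cb[shared]))
  num / (sqrt(sum(as.numeric(ca)^2)) * sqrt(sum(as.numeric(cb)^2)))
}

# k-mer count matrix (rows = proteins) with L2-normalised rows, over a given
# k-mer space
.kmer_matrix <- function(counts, space, ids) {
  M <- matrix(0, nrow = length(counts), ncol = length(space),
              dimnames = list(ids, space))
  for (i in seq_along(counts)) {
    hit <- intersect(names(counts[[i]]), space)
    if (length(hit)) M[i, hit] <- as.numeric(counts[[i]][hit])
  }
  nrm <- vapply(counts, function(cc) sqrt(sum(as.numeric(cc)^2)), numeric(1))
  nrm[nrm == 0] <- 1
  M / nrm
}

#' Build orthogroups by reciprocal best hits on k-mer similarity
#'
#' For every pair of genomes, each protein's best hit in the other genome is
#' found by cosine k-mer similarity (ties broken by lexicographic protein id);
#' reciprocal best hits with similarity >= `min_sim` become edges, and
#' connected components of the resulting graph are the orthogroups.
#' Singletons are excluded. This is a deliberately simple stand-in for a full
#' orthology inference; [read_orthogroup_table()] is the fidelity path for
#' users with real OrthoFinder output.
#'
#' @param proteomes named list (genome_id -> named character vector of protein
#'   sequences, names = protein ids).
#' @param k k-mer size (default 4).
#' @param min_sim minimum similarity for an edge (default 0.5).
#' @return an [orthogroup_table()].
#' @export
build_orthogroups_rbh <- function(proteomes, k = 4, min_sim = 0.5) {
  if (length(proteomes) < 2) stop("need at least 2 genomes")
  for (g in names(proteomes)) {
    if (!length(proteomes[[g]])) stop("empty proteome: ", g)
  }
  genomes <- names(proteomes)
  counts <- lapply(proteomes, function(seqs) lapply(seqs, .kmer_counts, k = k))
  # global protein index
  node_genome <- rep(genomes, vapply(proteomes, length, integer(1)))
  node_protein <- unlist(lapply(proteomes, names), use.names = FALSE)
  node_key <- paste(node_genome, node_protein, sep = "\r")
  parent <- seq_along(node_key)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }

  best_hits <- function(S, ids_b) {
    # for each row of S, best column; ties broken lexicographically on the
    # candidate protein id
    ord <- order(ids_b)
    vapply(seq_len(nrow(S)), function(i) {
      s <- S[i, ord]
      j <- which.max(s)               # first max = lexicographically smallest
      c(ord[j], unname(s[j]))
    }, numeric(2))
  }
  for (ia in seq_along(genomes)) {
    for (ib in seq_along(genomes)) {
      if (ib <= ia) next
      A <- genomes[ia]; B <- genomes[ib]
      space <- unique(c(unlist(lapply(counts[[A]], names), use.names = FALSE),
                        unlist(lapply(counts[[B]], names), use.names = FALSE)))
      MA <- .kmer_matrix(counts[[A]], space, names(proteomes[[A]]))
      MB <- .kmer_matrix(counts[[B]], space, names(proteomes[[B]]))
      S <- MA %*% t(MB)
      ab <- best_hits(S, colnames(S))
      ba <- best_hits(t(S), rownames(S))
      for (i in seq_len(ncol(ab))) {
        j <- ab[1, i]
        if (ab[2, i] >= min_sim && ba[1, j] == i) {
          ka <- paste(A, rownames(S)[i], sep = "\r")
          kb <- paste(B, colnames(S)[j], sep = "\r")
          union_(match(ka, node_key), match(kb, node_key))
        }
      }
    }
  }
  roots <- vapply(seq_along(node_key), find, integer(1))
  comp_size <- table(roots)
  keep <- comp_size[as.character(roots)] >= 2
  if (!any(keep)) {
    return(orthogroup_table(data.frame(orthogroup_id = character(),
                                       genome_id = character(),
                                       protein_id = character())))
  }
  comp <- roots[keep]
  og_id <- sprintf("OG%04d", match(comp, sort(unique(comp))))
  orthogroup_table(data.frame(orthogroup_id = og_id,
                              genome_id = node_genome[keep],
                              protein_id = node_protein[keep],
                              stringsAsFactors = FALSE))
}
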