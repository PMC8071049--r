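GENE_TABLE_COLUMNS <- c("genome_id", "contig_id", "ordinal", "start", "end",
                        "strand", "locus_tag", "gene_label", "product",
                        "orthogroup_id", "pseudo", "nif_gene", "nif_evidence")

#' Normalise a data frame into an ordered gene table
#'
#' A gene table is the substrate of operon detection: one row per gene feature,
#' sorted by contig and start coordinate, with per-contig 0-based ordinals.
#' Coordinates are 1-based inclusive (GenBank convention). Ordinals are always
#' recomputed from coordinates, never trusted from the input.
#'
#' @param df data frame with at least genome_id, contig_id, start, end, strand,
#'   locus_tag. Optional: gene_label, product, orthogroup_id, pseudo.
#' @param taxon_name optional organism name stored as an attribute.
#' @return data frame of class `gene_table` with columns
#'   `r paste(GENE_TABLE_COLUMNS, collapse = ", ")`.
#' @export
as_gene_table <- function(df, taxon_name = NULL) {
  required <- c("genome_id", "contig_id", "start", "end", "strand", "locus_tag")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("gene table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("gene_label", "product", "orthogroup_id", "nif_gene",
                "nif_evidence")) {
    if (is.null(df[[col]])) df[[col]] <- NA_character_
    df[[col]] <- as.character(df[[col]])
    df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA_character_
  }
  if (is.null(df[["pseudo"]])) df$pseudo <- FALSE
  df$pseudo <- as.logical(df$pseudo) %in% TRUE
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(is.na(df$start)) || any(is.na(df$end))) {
    stop("gene table has non-integer start/end coordinates")
  }
  if (any(df$end < df$start)) {
    bad <- df$locus_tag[df$end < df$start][1]
    stop("gene table has end < start at locus_tag ", bad)
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  if (length(unique(df$genome_id)) > 1) {
    stop("a gene table holds exactly one genome; got: ",
         paste(unique(df$genome_id), collapse = ", "))
  }
  dup <- df$locus_tag[duplicated(df$locus_tag)]
  if (length(dup)) {
    stop("duplicate locus_tag in gene table: ", dup[1])
  }
  # contigs keep their order of first appearance; rows sort by start within
  contig_rank <- match(df$contig_id, unique(df$contig_id))
  ord <- order(contig_rank, df$start, df$end, df$locus_tag)
  df <- df[ord, , drop = FALSE]
  df$ordinal <- unlist(lapply(split(seq_len(nrow(df)), match(df$contig_id, unique(df$contig_id))),
                              function(idx) seq_along(idx) - 1L), use.names = FALSE)
  df <- df[, GENE_TABLE_COLUMNS]
  rownames(df) <- NULL
  attr(df, "taxon_name") <- taxon_name %||% attr(df, "taxon_name") %||% unique(df$genome_id)
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Parse a GenBank flat file into a gene table
#'
#' Reads gene and CDS features (CDS preferred when both carry the same
#' locus_tag) from one or more records (contigs) of a GenBank flat file.
#' Compound locations (join/complement) are reduced to their minimal start and
#' maximal end. Features lacking a locus_tag get a generated stable tag
#' `<contig>_<ordinal>`. Features flagged `/pseudo` are parsed but marked.
#'
#' @param path path to a GenBank flat file (one or more records).
#' @param genome_id genome identifier; defaults to the file name without
#'   extension.
#' @return a [as_gene_table()] gene table.
#' @export
parse_genbank <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop("cannot read GenBank file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(gb|gbk|gbff|txt)$", "", basename(path))
  }
  taxon <- NA_character_
  feats <- list()
  contig <- NA_character_
  in_features <- FALSE
  cur <- NULL  # current feature: list(key, loc, quals)
  flush_feat <- function(cur) if (!is.null(cur)) feats[[length(feats) + 1L]] <<- cur
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (grepl("^LOCUS", line)) {
      flush_feat(cur); cur <- NULL
      tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
      if (length(tok) < 2) stop("unparseable LOCUS line at line ", i, ": ", line)
      contig <- tok[2]
      in_features <- FALSE
      next
    }
    if (grepl("^\\s*ORGANISM", line) && is.na(taxon)) {
      taxon <- trimws(sub("^\\s*ORGANISM", "", line))
      next
    }
    if (grepl("^FEATURES", line)) { in_features <- TRUE; next }
    if (grepl("^(ORIGIN|CONTIG|//)", line)) {
      flush_feat(cur); cur <- NULL
      in_features <- FALSE
      next
    }
    if (!in_features) next
    if (grepl("^ {5}\\S", line)) {           # new feature
      flush_feat(cur)
      key <- trimws(substr(line, 1, 20))
      loc <- trimws(substr(line, 21, nchar(line)))
      cur <- list(key = key, loc = loc, quals = character(), contig = contig,
                  line = i)
    } else if (!is.null(cur)) {
      txt <- trimws(line)
      if (startsWith(txt, "/")) {
        cur$quals <- c(cur$quals, txt)
      } else if (!length(cur$quals)) {
        cur$loc <- paste0(cur$loc, txt)   # wrapped location
      } else {
        cur$quals[length(cur$quals)] <- paste(cur$quals[length(cur$quals)], txt)
      }
    }
  }
  flush_feat(cur)

  feats <- Filter(function(f) f$key %in% c("gene", "CDS"), feats)
  if (!length(feats)) stop("empty annotation: no gene or CDS features in ", path)

  qual_value <- function(quals, name) {
    hit <- grep(paste0("^/", name, "(=|$)"), quals, value = TRUE)
    if (!length(hit)) return(NA_character_)
    v <- sub(paste0("^/", name, "=?"), "", hit[1])
    gsub('^"|"$', "", v)
  }
  rows <- lapply(feats, function(f) {
    nums <- suppressWarnings(as.integer(regmatches(f$loc, gregexpr("[0-9]+", f$loc))[[1]]))
    if (!length(nums) || any(is.na(nums))) {
      stop("unparseable feature location at line ", f$line, ": ", f$loc)
    }
    data.frame(genome_id = genome_id, contig_id = f$contig,
               start = min(nums), end = max(nums),
               strand = if (grepl("complement", f$loc)) "-" else "+",
               locus_tag = qual_value(f$quals, "locus_tag"),
               gene_label = qual_value(f$quals, "gene"),
               product = qual_value(f$quals, "product"),
               pseudo = any(grepl("^/pseudo(=|$)?", f$quals)),
               key = f$key,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  # prefer CDS over gene features sharing a locus_tag (or an identical span)
  fid <- ifelse(is.na(df$locus_tag),
                paste(df$contig_id, df$start, df$end, sep = ":"), df$locus_tag)
  keep <- rep(TRUE, nrow(df))
  for (id in unique(fid[duplicated(fid)])) {
    idx <- which(fid == id)
    if (any(df$key[idx] == "CDS")) keep[idx[df$key[idx] != "CDS"]] <- FALSE
    else keep[idx[-1]] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  df$key <- NULL
  # generated stable tags for features without locus_tag, per contig in
  # coordinate order
  for (ct in unique(df$contig_id)) {
    idx <- which(df$contig_id == ct)
    idx <- idx[order(df$start[idx], df$end[idx])]
    miss <- is.na(df$locus_tag[idx])
    if (any(miss)) {
      df$locus_tag[idx[miss]] <- paste0(ct, "_", which(miss) - 1L)
    }
  }
  as_gene_table(df, taxon_name = if (is.na(taxon)) genome_id else taxon)
}

#' Read a gene table from a TSV file
#'
#' Lightweight tab-separated alternative to GenBank input. Required columns:
#' genome_id, contig_id, start, end, strand, locus_tag. Optional: gene_label,
#' product, orthogroup_id, pseudo. Ordinals are recomputed from coordinates;
#' an ordinal column in the file is ignored.
#'
#' @param path path to a TSV file with a header row.
#' @return a gene table (see [as_gene_table()]).
#' @export
parse_gene_table <- function(path) {
  if (!file.exists(path)) stop("cannot read gene table: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  df$ordinal <- NULL
  as_gene_table(df)
}

#' Write a gene table to a TSV file
#'
#' @param x a gene table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Tag nif candidate genes by orthogroup membership
#'
#' A record whose protein belongs to an orthogroup mapped to a canonical nif
#' name gets that name in the `nif_gene` column (evidence "orthogroup"). A
#' record mapping to the fused name nifEN carries the label "nifEN" and counts
#' as both nifE and nifN in all operon template logic (see [nif_components()]).
#' Records annotated "nif*" without orthogroup support are flagged
#' "unconfirmed" and excluded from operon detection unless
#' `config$include_unconfirmed` is set. Pseudogene-flagged records are never
#' tagged. Coordinates, ordinals and record count are never modified.
#'
#' @param annotation a gene table.
#' @param orthogroups an [orthogroup_table()] whose protein ids are this
#'   genome's locus_tags.
#' @param catalog a [nif_catalog()] with a populated `orthogroup_map` (see
#'   [map_nif_orthogroups()]).
#' @param config a [nif_config()].
#' @param manual_additions optional data frame (genome_id, locus_tag, nif_gene)
#'   of curated assignments applied with evidence "manual".
#' @return the annotation with `nif_gene`, `nif_evidence` and `orthogroup_id`
#'   filled in.
#' @export
tag_nif_candidates <- function(annotation, orthogroups, catalog = nif_catalog(),
                               config = nif_config(), manual_additions = NULL) {
  stopifnot(inherits(annotation, "gene_table"))
  og_map <- catalog$orthogroup_map
  absent <- setdiff(names(og_map), unique(orthogroups$orthogroup_id))
  if (length(absent)) {
    warning("orthogroup id(s) in catalog absent from table: ",
            paste(absent, collapse = ", "))
  }
  genome <- unique(annotation$genome_id)
  og <- orthogroups[orthogroups$genome_id == genome, , drop = FALSE]
  hit <- match(annotation$locus_tag, og$protein_id)
  annotation$orthogroup_id <- ifelse(is.na(hit), annotation$orthogroup_id,
                                     og$orthogroup_id[hit])
  mapped <- og_map[annotation$orthogroup_id]
  mapped[is.na(annotation$orthogroup_id)] <- NA_character_
  annotation$nif_gene <- unname(mapped)
  annotation$nif_evidence <- ifelse(is.na(annotation$nif_gene), NA_character_,
                                    "orthogroup")
  # literal nif annotation without orthogroup support
  literal <- !is.na(annotation$gene_label) &
    grepl("^nif", annotation$gene_label, ignore.case = TRUE) &
    is.na(annotation$nif_gene)
  if (any(literal)) {
    lab <- annotation$gene_label[literal]
    known <- lab %in% c(catalog$gene_names, names(catalog$fused_names))
    annotation$nif_evidence[literal] <- "unconfirmed"
    if (config$include_unconfirmed) {
      annotation$nif_gene[which(literal)[known]] <- lab[known]
    }
  }
  if (!is.null(manual_additions)) {
    man <- manual_additions[manual_additions$genome_id == genome, , drop = FALSE]
    idx <- match(man$locus_tag, annotation$locus_tag)
    ok <- !is.na(idx)
    annotation$nif_gene[idx[ok]] <- man$nif_gene[ok]
    annotation$nif_evidence[idx[ok]] <- "manual"
  }
  # pseudogenes are parsed but never candidates
  annotation$nif_gene[annotation$pseudo] <- NA_character_
  annotation
}

`%||%` <- function(a, b) if (is.null(a)) b else a
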