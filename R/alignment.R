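AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")

.check_alignment <- function(alignment) {
  if (is.null(names(alignment)) || any(!nzchar(names(alignment)))) {
    stop("alignment rows must be named by taxon id")
  }
  if (anyDuplicated(names(alignment))) stop("duplicate taxa in alignment")
  L <- unique(nchar(alignment))
  if (length(L) != 1) stop("alignment rows differ in length")
  invisible(L)
}

.alignment_matrix <- function(alignment) {
  .check_alignment(alignment)
  do.call(rbind, strsplit(unname(alignment), ""))
}

#' Read / write an aligned FASTA file
#'
#' Thin wrappers around Biostrings that present alignments as named character
#' vectors (names = taxon ids, values = equal-length rows, gap "-").
#'
#' @param path file path.
#' @return `read_alignment_fasta`: named character vector.
#' @export
read_alignment_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @param alignment named character vector of sequences.
#' @rdname read_alignment_fasta
#' @return `write_alignment_fasta`: `path`, invisibly.
#' @export
write_alignment_fasta <- function(alignment, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(alignment), path)
  invisible(path)
}

#' Concatenate per-marker alignments into one partitioned alignment
#'
#' @param alignments named list of alignments (marker name -> named character
#'   vector), all indexed by the same taxon id space.
#' @param taxa taxon ids to include; default the taxa of the first marker.
#' @param fill_missing if `TRUE`, a taxon absent from a marker is filled with
#'   gaps; the default (`FALSE`) errors, matching complete marker sets.
#' @return named character vector with attribute `partitions`: a data frame
#'   (marker, start, end) tiling the columns (1-based, inclusive).
#' @export
concatenate_alignments <- function(alignments, taxa = NULL, fill_missing = FALSE) {
  if (anyDuplicated(names(alignments))) stop("duplicate marker names")
  if (is.null(taxa)) taxa <- names(alignments[[1]])
  pieces <- matrix("", nrow = length(taxa), ncol = length(alignments))
  parts <- data.frame(marker = names(alignments), start = NA_integer_,
                      end = NA_integer_, stringsAsFactors = FALSE)
  at <- 1L
  for (j in seq_along(alignments)) {
    aln <- alignments[[j]]
    L <- .check_alignment(aln)
    absent <- setdiff(taxa, names(aln))
    if (length(absent)) {
      if (!fill_missing) {
        stop("taxa missing from marker ", names(alignments)[j], ": ",
             paste(absent, collapse = ", "))
      }
      aln[absent] <- strrep("-", L)
    }
    pieces[, j] <- aln[taxa]
    parts$start[j] <- at
    parts$end[j] <- at + L - 1L
    at <- at + L
  }
  out <- apply(pieces, 1, paste, collapse = "")
  names(out) <- taxa
  attr(out, "partitions") <- parts
  out
}

#' Split a concatenated alignment back into its markers
#'
#' Inverse of [concatenate_alignments()], using the `partitions` attribute.
#'
#' @param concatenated output of [concatenate_alignments()].
#' @return named list of alignments.
#' @export
split_alignment <- function(concatenated) {
  parts <- attr(concatenated, "partitions")
  if (is.null(parts)) stop("no partitions attribute")
  out <- lapply(seq_len(nrow(parts)), function(j) {
    x <- substr(as.character(concatenated), parts$start[j], parts$end[j])
    names(x) <- names(concatenated)
    x
  })
  names(out) <- parts$marker
  out
}

#' Pairwise protein distances from an alignment
#'
#' Columns where either row has a gap are ignored pairwise. `model = "p"`
#' gives the proportion of mismatching compared columns; `model = "poisson"`
#' the Poisson correction -ln(1 - p). A pair with p = 1 under the Poisson
#' model is flagged saturated and set to `saturation_ceiling`.
#'
#' @param alignment named character vector of aligned sequences.
#' @param model "p" or "poisson".
#' @param saturation_ceiling distance assigned to saturated pairs (default 10).
#' @return symmetric matrix of distances with taxon dimnames and attribute
#'   `saturated` (logical matrix).
#' @export
protein_distance <- function(alignment, model = c("poisson", "p"),
                             saturation_ceiling = 10) {
  model <- match.arg(model)
  M <- .alignment_matrix(alignment)
  n <- nrow(M)
  if (n < 2) stop("need at least 2 taxa")
  taxa <- names(alignment)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  sat <- matrix(FALSE, n, n, dimnames = list(taxa, taxa))
  gap <- M == "-"
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      ncomp <- sum(ok)
      if (ncomp == 0) {
        stop("no comparable columns between ", taxa[i], " and ", taxa[j])
      }
      p <- sum(M[i, ok] != M[j, ok]) / ncomp
      if (model == "p") {
        d <- p
      } else if (p >= 1) {
        d <- saturation_ceiling
        sat[i, j] <- sat[j, i] <- TRUE
      } else {
        d <- -log(1 - p)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  attr(D, "saturated") <- sat
  D
}
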