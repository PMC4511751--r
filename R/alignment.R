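#' Construct a haplotype alignment
#'
#' A `haplotype_alignment` holds equal-length phased haplotype sequences
#' together with a per-column site classification. Columns containing a gap
#' character in any sequence are classed `"indel"`; columns with more than one
#' non-missing base among the remainder are `"substitution"`; all others are
#' `"invariant"`. `'N'` is treated as missing data and never makes a column
#' polymorphic on its own.
#'
#' @param sequences character vector of sequences over `{A,C,G,T,-,N}`
#'   (lowercase accepted, uppercased on construction), all the same length.
#' @param ids character vector of unique, non-empty record identifiers.
#' @param positions optional integer vector of 1-based genomic anchor
#'   positions, one per column (e.g. reference-chromosome coordinates used to
#'   label sites in reports). Defaults to `1:length`.
#'
#' @return An object of class `haplotype_alignment`: a list with elements
#'   `ids`, `matrix` (character matrix, rows = chromosomes), `length`,
#'   `site_classes` and `positions`.
#' @export
#' @examples
#' aln <- haplotype_alignment(c("ACGT", "ACCT"), c("h1", "h2"))
#' aln$site_classes
haplotype_alignment <- function(sequences, ids = names(sequences),
                                positions = NULL) {
  if (length(sequences) == 0L) stop("alignment must contain at least one sequence")
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate sequence ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(ids))) stop("sequence ids must be non-empty")
  sequences <- toupper(as.character(sequences))
  lens <- nchar(sequences)
  if (any(lens == 0L)) stop("empty sequence for record ", ids[which(lens == 0L)[1L]])
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])[1L]
    stop("sequence lengths differ: record '", ids[bad], "' has length ",
         lens[bad], ", expected ", lens[1L])
  }
  chars <- strsplit(sequences, "", fixed = TRUE)
  mat <- do.call(rbind, chars)
  rownames(mat) <- ids
  ok <- mat %in% c("A", "C", "G", "T", "-", "N")
  if (!all(ok)) {
    bad <- unique(mat[!ok])
    stop("invalid characters in alignment: ", paste(bad, collapse = ", "))
  }
  L <- lens[1L]
  if (is.null(positions)) positions <- seq_len(L)
  if (length(positions) != L) stop("positions must have one entry per column")
  structure(
    list(ids = ids, matrix = mat, length = L,
         site_classes = classify_columns(mat),
         positions = as.integer(positions)),
    class = "haplotype_alignment")
}

classify_columns <- function(mat) {
  apply(mat, 2L, function(col) {
    if (any(col == "-")) return("indel")
    col <- col[col != "N"]
    if (length(unique(col)) > 1L) "substitution" else "invariant"
  })
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  tab <- table(factor(x$site_classes,
                      levels = c("invariant", "substitution", "indel")))
  cat("haplotype_alignment: ", length(x$ids), " chromosomes, ",
      x$length, " bp\n", sep = "")
  cat("  sites: ", tab[["substitution"]], " substitution, ",
      tab[["indel"]], " indel, ", tab[["invariant"]], " invariant\n", sep = "")
  invisible(x)
}

#' Extract sequences as a character vector
#' @param alignment a [haplotype_alignment()].
#' @param ids optional subset of record ids (default all).
#' @return named character vector of sequences.
#' @export
alignment_sequences <- function(alignment, ids = alignment$ids) {
  stopifnot(inherits(alignment, "haplotype_alignment"))
  missing <- setdiff(ids, alignment$ids)
  if (length(missing)) stop("unknown chromosome ids: ", paste(missing, collapse = ", "))
  apply(alignment$matrix[ids, , drop = FALSE], 1L, paste, collapse = "")
}

#' Columns usable for site-based summary statistics
#'
#' Indel and missing-data columns are excluded from segregating-site counts
#' and per-site diversity denominators, following the convention of standard
#' polymorphism software. A column is "missing" here if every row is `'N'`.
#'
#' @param alignment a [haplotype_alignment()].
#' @return integer vector of column indices.
#' @export
comparable_sites <- function(alignment) {
  stopifnot(inherits(alignment, "haplotype_alignment"))
  keep <- alignment$site_classes != "indel"
  all_n <- apply(alignment$matrix, 2L, function(col) all(col == "N"))
  which(keep & !all_n)
}

#' Count segregating sites
#'
#' @param alignment a [haplotype_alignment()].
#' @param chromosomes optional subset of record ids.
#' @return integer count of substitution columns (indel and all-missing
#'   columns excluded) segregating within the chosen chromosomes.
#' @export
segregating_sites <- function(alignment, chromosomes = alignment$ids) {
  sub <- subset_alignment(alignment, chromosomes)
  sum(sub$site_classes == "substitution")
}

#' Restrict an alignment to a subset of chromosomes
#' @param alignment a [haplotype_alignment()].
#' @param chromosomes record ids to keep.
#' @return a [haplotype_alignment()] with site classes recomputed.
#' @export
subset_alignment <- function(alignment, chromosomes) {
  stopifnot(inherits(alignment, "haplotype_alignment"))
  missing <- setdiff(chromosomes, alignment$ids)
  if (length(missing)) stop("unknown chromosome ids: ", paste(missing, collapse = ", "))
  haplotype_alignment(
    apply(alignment$matrix[chromosomes, , drop = FALSE], 1L, paste, collapse = ""),
    ids = chromosomes, positions = alignment$positions)
}
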