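#' Read an aligned FASTA file as a haplotype alignment
#'
#' Sequences must be pre-aligned (equal length). Lowercase bases are
#' uppercased; characters outside `{A,C,G,T,-,N}` are rejected. Record order
#' is preserved and per-column site classes are computed on read.
#'
#' @param path path to a FASTA file.
#' @return a [haplotype_alignment()].
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  haplotype_alignment(as.character(seqs), ids = ids)
}

#' Write a haplotype alignment to FASTA
#'
#' @param alignment a [haplotype_alignment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "haplotype_alignment"))
  seqs <- Biostrings::BStringSet(alignment_sequences(alignment))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a chromosome-to-population map
#'
#' The map is a two-column TSV with header `chromosome_id<TAB>population`.
#' Every chromosome id must name a record of the companion alignment; a
#' diploid individual contributes two rows (one per phased chromosome).
#'
#' @param path path to the TSV file.
#' @param alignment the companion [haplotype_alignment()] used for
#'   validation.
#' @return a `population_map`: a data.frame with columns `chromosome_id` and
#'   `population` (factor, levels in file order).
#' @export
read_population_map <- function(path, alignment) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("chromosome_id", "population") %in% names(df)))
    stop("population map must have columns 'chromosome_id' and 'population'")
  population_map(df$chromosome_id, df$population, alignment = alignment)
}

#' Construct a population map
#'
#' @param chromosome_id character vector of chromosome (haplotype) ids.
#' @param population character vector of population labels, recycled if of
#'   length one.
#' @param alignment optional [haplotype_alignment()]; if given, every id must
#'   match one of its records.
#' @return a `population_map` data.frame.
#' @export
population_map <- function(chromosome_id, population, alignment = NULL) {
  if (length(population) == 1L)
    population <- rep(population, length(chromosome_id))
  stopifnot(length(chromosome_id) == length(population))
  if (anyDuplicated(chromosome_id))
    stop("duplicate chromosome ids in population map: ",
         paste(unique(chromosome_id[duplicated(chromosome_id)]), collapse = ", "))
  if (!is.null(alignment)) {
    missing <- setdiff(chromosome_id, alignment$ids)
    if (length(missing))
      stop("population map references unknown chromosome ids: ",
           paste(missing, collapse = ", "))
  }
  structure(
    data.frame(chromosome_id = as.character(chromosome_id),
               population = factor(population, levels = unique(population)),
               stringsAsFactors = FALSE),
    class = c("population_map", "data.frame"))
}

#' Write result tables with a reproducibility manifest
#'
#' Each data.frame in `tables` is written as a TSV named after its list
#' element; each igraph object is written as GraphML. A `manifest.json`
#' recording the run parameters (including any RNG seed in `params`) and the
#' written file list is always produced, so two runs with the same seed give
#' byte-identical outputs.
#'
#' @param tables named list of data.frames and/or `igraph` graphs.
#' @param path output directory (created if absent).
#' @param params named list of run parameters recorded in the manifest;
#'   should include `seed` whenever randomness was involved.
#' @return character vector of written file paths, invisibly.
#' @export
write_summary <- function(tables, path, params = list()) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  if (length(tables) && is.null(names(tables)))
    stop("'tables' must be a named list")
  if (length(tables) == 0L)
    warning("no result tables supplied; writing manifest only")
  written <- character(0)
  for (nm in names(tables)) {
    obj <- tables[[nm]]
    if (inherits(obj, "igraph")) {
      f <- file.path(path, paste0(nm, ".graphml"))
      igraph::write_graph(obj, f, format = "graphml")
    } else {
      f <- file.path(path, paste0(nm, ".tsv"))
      df <- as.data.frame(obj)
      df <- df[, sort(names(df)), drop = FALSE]
      utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    written <- c(written, f)
  }
  manifest <- file.path(path, "manifest.json")
  jsonlite::write_json(
    list(parameters = params, files = basename(written)),
    manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  written <- c(written, manifest)
  invisible(written)
}
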