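# Population differentiation (Hudson F_ST), island-model migration
# estimates, and haplotype sharing spectra.

pairwise_diff_matrix <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      a <- mat[i, ]; b <- mat[j, ]
      ok <- a != "N" & b != "N"
      d[i, j] <- d[j, i] <- sum(a[ok] != b[ok])
    }
  }
  d
}

#' Pairwise F_ST between two populations
#'
#' Hudson-Slatkin-Maddison estimator `1 - Hw / Hb`, where `Hw` is the mean
#' within-population pairwise difference (unweighted average of the two
#' populations) and `Hb` the mean between-population pairwise difference,
#' both over comparable (non-indel) sites.
#'
#' @param alignment a [haplotype_alignment()].
#' @param map a [population_map()].
#' @param pop_a,pop_b population labels present in `map`.
#' @return list with `pop_a`, `pop_b`, `fst` (`NA` when `Hb = 0`, i.e.
#'   identical populations) and `nm` (from [nm_from_fst()], `Inf` when
#'   `fst <= 0`).
#' @export
pairwise_fst <- function(alignment, map, pop_a, pop_b) {
  stopifnot(inherits(alignment, "haplotype_alignment"),
            inherits(map, "population_map"))
  ids_a <- map$chromosome_id[map$population == pop_a]
  ids_b <- map$chromosome_id[map$population == pop_b]
  if (length(ids_a) < 2L || length(ids_b) < 2L)
    stop("need at least 2 chromosomes in each population")
  sites <- comparable_sites(alignment)
  mat <- alignment$matrix[c(ids_a, ids_b), sites, drop = FALSE]
  d <- pairwise_diff_matrix(mat)
  na <- length(ids_a); nb <- length(ids_b)
  ia <- seq_len(na); ib <- seq.int(na + 1L, na + nb)
  hw_a <- mean(d[ia, ia][upper.tri(d[ia, ia])])
  hw_b <- mean(d[ib, ib][upper.tri(d[ib, ib])])
  hb <- mean(d[ia, ib])
  fst <- if (hb == 0) NA_real_ else 1 - mean(c(hw_a, hw_b)) / hb
  list(pop_a = pop_a, pop_b = pop_b, fst = fst,
       nm = if (is.na(fst)) NA_real_ else nm_from_fst(fst))
}

#' Convert between F_ST and the island-model migration parameter Nm
#'
#' Under the island-model equilibrium `F_ST = 1 / (1 + 4 Nm)`, so
#' `Nm = (1 - F_ST) / (4 F_ST)`. The two functions are exact inverses on
#' `(0, 1]`. Non-positive `fst` (no detectable differentiation) maps to
#' `Inf` migration.
#'
#' @param fst differentiation estimate.
#' @param nm migration estimate (migrants per generation).
#' @return the converted value.
#' @export
#' @examples
#' nm_from_fst(0.5)        # 0.25
#' fst_from_nm(12.02)      # ~0.02
nm_from_fst <- function(fst) {
  if (is.na(fst)) return(NA_real_)
  if (fst > 1) stop("fst cannot exceed 1")
  if (fst <= 0) return(Inf)
  (1 - fst) / (4 * fst)
}

#' @rdname nm_from_fst
#' @export
fst_from_nm <- function(nm) {
  if (is.na(nm)) return(NA_real_)
  if (nm < 0) stop("nm must be non-negative")
  1 / (1 + 4 * nm)
}

#' All pairwise F_ST / Nm values
#'
#' @param alignment a [haplotype_alignment()].
#' @param map a [population_map()].
#' @return data.frame with one row per unordered population pair and columns
#'   `pop_a`, `pop_b`, `fst`, `nm`.
#' @export
fst_matrix <- function(alignment, map) {
  pops <- levels(map$population)
  pairs <- utils::combn(pops, 2L)
  rows <- apply(pairs, 2L, function(p) {
    r <- pairwise_fst(alignment, map, p[1L], p[2L])
    data.frame(pop_a = r$pop_a, pop_b = r$pop_b, fst = r$fst, nm = r$nm,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Haplotype spectrum and sharing fractions per population
#'
#' Identical sequences (over the full alignment, indel characters included)
#' collapse to one haplotype. A haplotype is private when observed in exactly
#' one population; the shared/private fractions of a population are computed
#' over its chromosomes, so they always sum to 1. With a single population
#' every haplotype is private by definition.
#'
#' @param alignment a [haplotype_alignment()].
#' @param map a [population_map()].
#' @return list with `table` (per-population haplotype counts and
#'   frequencies: columns `population`, `haplotype`, `count`, `frequency`,
#'   `private`) and `sharing` (per-population `shared_fraction`,
#'   `private_fraction`).
#' @export
haplotype_spectrum <- function(alignment, map) {
  stopifnot(inherits(alignment, "haplotype_alignment"),
            inherits(map, "population_map"))
  seqs <- alignment_sequences(alignment, map$chromosome_id)
  hap_ids <- match(seqs, unique(seqs))
  hap_label <- paste0("H", hap_ids)
  pops <- map$population
  tab <- as.data.frame(table(population = pops, haplotype = hap_label),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, ]
  names(tab)[names(tab) == "Freq"] <- "count"
  pop_n <- table(pops)
  tab$frequency <- tab$count / as.numeric(pop_n[tab$population])
  npops_per_hap <- tapply(tab$population, tab$haplotype,
                          function(p) length(unique(p)))
  tab$private <- npops_per_hap[tab$haplotype] == 1L
  sharing <- do.call(rbind, lapply(levels(pops), function(p) {
    sub <- tab[tab$population == p, ]
    priv <- sum(sub$count[sub$private]) / sum(sub$count)
    data.frame(population = p, shared_fraction = 1 - priv,
               private_fraction = priv, stringsAsFactors = FALSE)
  }))
  rownames(tab) <- rownames(sharing) <- NULL
  tab <- tab[order(tab$population, tab$haplotype), ]
  list(table = tab, sharing = sharing)
}
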