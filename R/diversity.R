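#' Nucleotide diversity (pi) per site
#'
#' Mean number of pairwise differences between chromosomes, averaged over all
#' unordered pairs and divided by the number of comparable sites (columns
#' that are neither indel nor entirely missing). Sites where either member of
#' a pair is 'N' are skipped for that pair without adjusting the denominator;
#' fixtures in this package carry no partial missingness.
#'
#' @param alignment a [haplotype_alignment()].
#' @param chromosomes optional subset of record ids (default: all).
#' @return nucleotide diversity per site, a fraction in `[0, 1]`.
#' @export
#' @examples
#' aln <- haplotype_alignment(c("AAAA", "AAAT"), c("a", "b"))
#' nucleotide_diversity(aln)  # 1 mismatch / 4 sites = 0.25
nucleotide_diversity <- function(alignment, chromosomes = alignment$ids) {
  stopifnot(inherits(alignment, "haplotype_alignment"))
  n <- length(chromosomes)
  if (n < 2L) stop("nucleotide diversity needs at least 2 chromosomes")
  sites <- comparable_sites(alignment)
  if (length(sites) == 0L) stop("no comparable (non-indel) sites in alignment")
  mat <- alignment$matrix[chromosomes, sites, drop = FALSE]
  total <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      a <- mat[i, ]; b <- mat[j, ]
      ok <- a != "N" & b != "N"
      total <- total + sum(a[ok] != b[ok])
    }
  }
  total / choose(n, 2) / length(sites)
}

#' Watterson's theta per site
#'
#' `S / (a_{n-1} * L)` with `a_{n-1} = sum_{i=1}^{n-1} 1/i`, the standard
#' segregating-sites estimator of the population mutation rate per site.
#'
#' @param S number of segregating sites.
#' @param n_chromosomes sample size in chromosomes (2 per diploid individual).
#' @param effective_length number of comparable sites the `S` was counted
#'   over.
#' @return theta per site, a fraction.
#' @export
#' @examples
#' watterson_theta(15, 1194, 1002)  # ~0.00195
watterson_theta <- function(S, n_chromosomes, effective_length) {
  if (n_chromosomes < 2L) stop("Watterson's theta needs n >= 2 chromosomes")
  if (effective_length <= 0) stop("effective_length must be positive")
  if (S < 0) stop("S must be non-negative")
  a1 <- sum(1 / seq_len(n_chromosomes - 1L))
  S / (a1 * effective_length)
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' Normalized difference between the pairwise-diversity and segregating-sites
#' estimators of theta, using the original variance constants
#' (a1, a2, b1, b2, c1, c2, e1, e2). Negative values indicate an excess of
#' rare variants; positive values an excess of intermediate-frequency
#' variants.
#'
#' @param pi nucleotide diversity per site.
#' @param S number of segregating sites.
#' @param n_chromosomes sample size in chromosomes.
#' @param effective_length comparable-site count that `pi` and `S` refer to.
#' @return D, or `NA_real_` (undefined) when `S = 0`.
#' @export
tajimas_d <- function(pi, S, n_chromosomes, effective_length) {
  if (n_chromosomes < 2L) stop("Tajima's D needs n >= 2 chromosomes")
  if (S == 0) return(NA_real_)
  k <- tajima_constants(n_chromosomes)
  num <- pi * effective_length - S / k$a1
  num / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Monte-Carlo p-value for Tajima's D
#'
#' Two-sided probability `Pr(|D_sim| >= |d_obs|)` under the standard neutral
#' coalescent with no recombination, mutations arriving as a Poisson process
#' along lineages at a fixed population mutation rate `theta * length` per
#' locus (not conditioned on the observed S). Replicates with `S = 0` leave D
#' undefined and are dropped from the tail probability.
#'
#' @param d_obs observed Tajima's D.
#' @param n_chromosomes sample size in chromosomes.
#' @param theta per-site mutation parameter used for the null (typically the
#'   observed Watterson theta).
#' @param effective_length comparable-site count.
#' @param replicates number of coalescent replicates (>= 100).
#' @param seed integer RNG seed; the result is deterministic given the seed.
#' @return two-sided p-value, or `NA_real_` when `theta = 0`.
#' @export
tajima_d_pvalue <- function(d_obs, n_chromosomes, theta, effective_length,
                            replicates = 10000L, seed = 1L) {
  if (replicates < 100L) stop("use at least 100 replicates")
  if (theta <= 0) return(NA_real_)
  theta_locus <- theta * effective_length
  set.seed(seed)
  n <- n_chromosomes
  d_sim <- vapply(seq_len(replicates), function(i) {
    cc <- coalescent_carrier_counts(n, theta_locus)
    S <- length(cc)
    if (S == 0L) return(NA_real_)
    pi_total <- sum(2 * cc * (n - cc)) / (n * (n - 1))
    tajimas_d(pi_total / effective_length, S, n, effective_length)
  }, numeric(1))
  d_sim <- d_sim[!is.na(d_sim)]
  if (length(d_sim) == 0L) return(NA_real_)
  mean(abs(d_sim) >= abs(d_obs))
}

#' Per-population diversity summary table
#'
#' One row per population (plus a pooled `All` row if requested) with sample
#' size, segregating sites, haplotype count, pi, Watterson's theta and
#' Tajima's D. Statistics are stored as fractions; multiply by 100 for the
#' conventional percent display.
#'
#' @param alignment a [haplotype_alignment()].
#' @param map a [population_map()].
#' @param pooled also compute a pooled row across all chromosomes.
#' @param d_pvalues if `TRUE`, attach a Monte-Carlo p-value per row (slow).
#' @param replicates,seed passed to [tajima_d_pvalue()] when `d_pvalues`.
#' @return data.frame with columns `population`, `n_chromosomes`, `S`,
#'   `n_haplotypes`, `pi`, `theta_w`, `tajima_d` (and `d_pvalue`).
#' @export
diversity_summary <- function(alignment, map, pooled = TRUE,
                              d_pvalues = FALSE, replicates = 2000L,
                              seed = 1L) {
  stopifnot(inherits(alignment, "haplotype_alignment"),
            inherits(map, "population_map"))
  groups <- split(map$chromosome_id, map$population)
  if (pooled) groups <- c(groups, list(All = map$chromosome_id))
  rows <- lapply(names(groups), function(pop) {
    ids <- groups[[pop]]
    n <- length(ids)
    S <- segregating_sites(alignment, ids)
    h <- length(unique(alignment_sequences(alignment, ids)))
    L <- length(comparable_sites(alignment))
    pi <- if (n >= 2L) nucleotide_diversity(alignment, ids) else NA_real_
    th <- if (n >= 2L) watterson_theta(S, n, L) else NA_real_
    D <- if (n >= 2L) tajimas_d(pi, S, n, L) else NA_real_
    out <- data.frame(population = pop, n_chromosomes = n, S = S,
                      n_haplotypes = h, pi = pi, theta_w = th, tajima_d = D,
                      stringsAsFactors = FALSE)
    if (d_pvalues)
      out$d_pvalue <- if (!is.na(D) && th > 0)
        tajima_d_pvalue(D, n, th, L, replicates, seed) else NA_real_
    out
  })
  do.call(rbind, rows)
}
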