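# Poisson star-phylogeny age bound for a cluster of identical haplotypes.

#' Upper age bound for an identical-haplotype cluster
#'
#' If `n` copies of a haplotype descend independently from a common ancestor
#' `t` years ago (star phylogeny), the total branch length monitored is
#' `n * t` years, and the number of mutations observed over `length_bp`
#' sites is Poisson with mean `n * length_bp * mu * t`. Observing zero
#' mutations is compatible with age `t` at level `alpha` as long as
#' `exp(-n * L * mu * t) > alpha`; the bound reported is the largest integer
#' year satisfying the strict inequality, alongside the continuous solution
#' `-log(alpha) / (n * L * mu)`. The star assumption is conservative: any
#' true genealogy has less total branch length, so the bound is an
#' overestimate of the permissible age.
#'
#' @param n number of sampled copies of the haplotype.
#' @param length_bp monitored sequence length (bp).
#' @param mu mutation rate per site per year.
#' @param alpha probability threshold in (0, 1).
#' @return list with `n`, `length_bp`, `mu`, `alpha`, `rate_per_year`
#'   (`n * L * mu`), `t_upper_years` (largest integer year) and
#'   `t_continuous_years`.
#' @export
#' @examples
#' poisson_upper_bound(23, 1e4, 1e-9, 0.05)$t_upper_years  # 13024
poisson_upper_bound <- function(n, length_bp, mu, alpha) {
  stopifnot(n > 0, length_bp > 0, mu > 0)
  if (alpha >= 1) {
    warning("alpha >= 1 leaves no admissible age; returning 0")
    return(list(n = n, length_bp = length_bp, mu = mu, alpha = alpha,
                rate_per_year = n * length_bp * mu, t_upper_years = 0L,
                t_continuous_years = 0))
  }
  if (alpha <= 0) stop("alpha must lie in (0, 1)")
  rate <- n * length_bp * mu
  t_cont <- -log(alpha) / rate
  # survival is strictly decreasing, so the largest integer t with
  # exp(-rate * t) > alpha is floor(t_cont), stepping down when t_cont is
  # itself an integer (strict inequality)
  t_int <- floor(t_cont)
  if (exp(-rate * t_int) <= alpha) t_int <- t_int - 1L
  list(n = n, length_bp = length_bp, mu = mu, alpha = alpha,
       rate_per_year = rate, t_upper_years = as.integer(t_int),
       t_continuous_years = t_cont)
}

#' Expected waiting time for a single mutation on one lineage
#'
#' Mean waiting time `1 / (L * mu)` years for the first mutation to appear
#' anywhere in a monitored region of `length_bp` sites on a single lineage.
#'
#' @param length_bp monitored sequence length (bp).
#' @param mu mutation rate per site per year.
#' @return expected waiting time in years.
#' @export
#' @examples
#' single_mutation_waiting_time(6411, 1e-9)  # ~156000 years
single_mutation_waiting_time <- function(length_bp, mu) {
  stopifnot(length_bp > 0, mu > 0)
  1 / (length_bp * mu)
}
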