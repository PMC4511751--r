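# Synthetic-data generators: neutral coalescent alignments, island-model
# samples, star-phylogeny haplotype sets, and dose-response fixtures.
# Time is measured in units of 2N generations throughout the coalescent
# code, so the expected total branch length for n lineages is 2*a_{n-1}
# and E[S] = theta * a_{n-1} with mutations Poisson(theta/2 per unit
# branch length).

# Simulate one neutral coalescent genealogy and return, for each mutation,
# the number of sampled chromosomes carrying it (its subtended leaf count).
# Used both to build sequences and, on its own, as a fast null for Tajima's
# D. Does not touch the RNG seed; callers manage seeding.
coalescent_carrier_counts <- function(n, theta_locus) {
  sizes <- rep(1L, n)
  counts <- integer(0)
  k <- n
  while (k > 1L) {
    t_k <- stats::rexp(1L, rate = k * (k - 1) / 2)
    n_mut <- stats::rpois(1L, theta_locus / 2 * k * t_k)
    if (n_mut > 0L)
      counts <- c(counts, sizes[sample.int(k, n_mut, replace = TRUE)])
    pair <- sample.int(k, 2L)
    sizes[pair[1L]] <- sizes[pair[1L]] + sizes[pair[2L]]
    sizes <- sizes[-pair[2L]]
    k <- k - 1L
  }
  counts
}

# As above but returning the leaf-index sets of each mutation, for sequence
# construction.
coalescent_carrier_sets <- function(n, theta_locus) {
  members <- lapply(seq_len(n), identity)
  sets <- list()
  k <- n
  while (k > 1L) {
    t_k <- stats::rexp(1L, rate = k * (k - 1) / 2)
    n_mut <- stats::rpois(1L, theta_locus / 2 * k * t_k)
    if (n_mut > 0L) {
      hit <- sample.int(k, n_mut, replace = TRUE)
      sets <- c(sets, members[hit])
    }
    pair <- sample.int(k, 2L)
    members[[pair[1L]]] <- c(members[[pair[1L]]], members[[pair[2L]]])
    members <- members[-pair[2L]]
    k <- k - 1L
  }
  sets
}

# Place mutations on distinct sites (infinite-sites) and build sequences
# from a random root. carrier_sets: list of leaf-index vectors.
build_alignment_from_mutations <- function(n, length_bp, carrier_sets, ids) {
  S <- length(carrier_sets)
  if (S > length_bp)
    stop("more mutations (", S, ") than sites (", length_bp,
         "); increase length_bp or lower theta")
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, length_bp, replace = TRUE)
  mat <- matrix(rep(root, each = n), nrow = n)
  if (S > 0L) {
    pos <- sample.int(length_bp, S)
    for (m in seq_len(S)) {
      ref <- root[pos[m]]
      alt <- sample(setdiff(bases, ref), 1L)
      mat[carrier_sets[[m]], pos[m]] <- alt
    }
  }
  haplotype_alignment(apply(mat, 1L, paste, collapse = ""), ids = ids)
}

#' Simulate a neutral coalescent sample of aligned haplotypes
#'
#' Standard (Hudson-style) neutral coalescent with no recombination and
#' infinite-sites mutation: mutations arrive as a Poisson process at rate
#' `theta/2` per unit of coalescent branch length (time in units of 2N
#' generations), each hitting a distinct uniformly chosen site, so
#' `E[S] = theta * a_{n-1}` and `E[pi * L] = theta`.
#'
#' @param n_chromosomes sample size (>= 2).
#' @param theta population mutation parameter per locus (4Nu * L).
#' @param length_bp sequence length in bp.
#' @param seed integer RNG seed.
#' @return a [haplotype_alignment()] with ids `chr1..chrn`.
#' @export
simulate_coalescent_alignment <- function(n_chromosomes, theta, length_bp,
                                          seed = 1L) {
  stopifnot(n_chromosomes >= 2L, theta >= 0, length_bp >= 1L)
  set.seed(seed)
  sets <- coalescent_carrier_sets(n_chromosomes, theta)
  build_alignment_from_mutations(n_chromosomes, length_bp, sets,
                                 paste0("chr", seq_len(n_chromosomes)))
}

#' Simulate samples from a symmetric island model
#'
#' Structured coalescent in `n_demes` demes of equal size N: within-deme
#' coalescence at rate `k_i (k_i - 1) / 2` (time in 2N-generation units) and
#' per-lineage backward migration at rate `2 * nm` to a uniformly chosen
#' other deme. At equilibrium with many demes this yields pairwise
#' differentiation near `F_ST = 1 / (1 + 4 Nm (d/(d-1))^2)`. With `nm = 0`,
#' demes never share ancestry, so a finite `t_split` (time, in 2N units, at
#' which all demes fuse into one ancestral deme) must be given; a large
#' `t_split` then produces deeply diverged demes with `F_ST` near 1.
#'
#' @param n_demes number of demes (>= 2).
#' @param sample_size chromosomes sampled per deme.
#' @param nm migration parameter Nm (migrants per deme per generation).
#' @param theta mutation parameter per locus (same scaling as
#'   [simulate_coalescent_alignment()]).
#' @param length_bp sequence length in bp.
#' @param seed integer RNG seed.
#' @param t_split optional ancestral fusion time in 2N units (default `Inf`,
#'   permissible only when `nm > 0`).
#' @return list with elements `alignment` (a [haplotype_alignment()]) and
#'   `map` (a [population_map()] labelling demes `deme1..deme<d>`).
#' @export
simulate_island_samples <- function(n_demes, sample_size, nm, theta,
                                    length_bp, seed = 1L, t_split = Inf) {
  stopifnot(n_demes >= 2L, sample_size >= 1L, nm >= 0, theta >= 0)
  if (nm == 0 && !is.finite(t_split))
    stop("with nm = 0 demes never coalesce; supply a finite t_split")
  set.seed(seed)
  n <- n_demes * sample_size
  deme <- rep(seq_len(n_demes), each = sample_size)
  members <- lapply(seq_len(n), identity)
  sets <- list()
  time <- 0
  merged <- FALSE
  while (length(members) > 1L) {
    k <- length(members)
    k_per <- tabulate(deme, nbins = n_demes)
    coal_rates <- k_per * (k_per - 1) / 2
    mig_rate <- if (merged) 0 else 2 * nm * k
    total <- sum(coal_rates) + mig_rate
    if (total == 0) {
      # all lineages isolated; jump straight to the ancestral fusion
      dt <- t_split - time
      n_mut <- stats::rpois(1L, theta / 2 * k * dt)
      if (n_mut > 0L)
        sets <- c(sets, members[sample.int(k, n_mut, replace = TRUE)])
      time <- t_split
      deme[] <- 1L
      merged <- TRUE
      next
    }
    dt <- stats::rexp(1L, rate = total)
    if (!merged && time + dt > t_split) {
      dt <- t_split - time
      n_mut <- stats::rpois(1L, theta / 2 * k * dt)
      if (n_mut > 0L)
        sets <- c(sets, members[sample.int(k, n_mut, replace = TRUE)])
      time <- t_split
      deme[] <- 1L
      merged <- TRUE
      next
    }
    time <- time + dt
    n_mut <- stats::rpois(1L, theta / 2 * k * dt)
    if (n_mut > 0L)
      sets <- c(sets, members[sample.int(k, n_mut, replace = TRUE)])
    if (stats::runif(1L) < sum(coal_rates) / total) {
      d <- sample.int(n_demes, 1L, prob = coal_rates)
      in_d <- which(deme == d)
      pair <- in_d[sample.int(length(in_d), 2L)]
      members[[pair[1L]]] <- c(members[[pair[1L]]], members[[pair[2L]]])
      members <- members[-pair[2L]]
      deme <- deme[-pair[2L]]
    } else {
      lin <- sample.int(k, 1L)
      deme[lin] <- sample(setdiff(seq_len(n_demes), deme[lin]), 1L)
    }
  }
  ids <- paste0("deme", rep(seq_len(n_demes), each = sample_size),
                "_chr", rep(seq_len(sample_size), n_demes))
  aln <- build_alignment_from_mutations(n, length_bp, sets, ids)
  list(alignment = aln,
       map = population_map(ids, paste0("deme", rep(seq_len(n_demes),
                                                    each = sample_size)),
                            alignment = aln))
}

#' Generate a star-phylogeny haplotype set
#'
#' `n` copies of a common ancestral haplotype, each lineage independently
#' accumulating `Poisson(length_bp * mu * t_years)` mutations at distinct
#' uniformly chosen sites. This is the genealogy under which the Poisson age
#' bound ([poisson_upper_bound()]) is exact: total branch length `n * t`.
#'
#' @param n_chromosomes number of descendant copies.
#' @param length_bp monitored sequence length in bp.
#' @param mu mutation rate per site per year.
#' @param t_years age of the star (years).
#' @param seed integer RNG seed.
#' @return a [haplotype_alignment()].
#' @export
generate_star_haplotypes <- function(n_chromosomes, length_bp, mu, t_years,
                                     seed = 1L) {
  stopifnot(n_chromosomes >= 1L, length_bp >= 1L, mu >= 0, t_years >= 0)
  set.seed(seed)
  per_lineage <- stats::rpois(n_chromosomes, length_bp * mu * t_years)
  sets <- rep(as.list(seq_len(n_chromosomes)), per_lineage)
  build_alignment_from_mutations(n_chromosomes, length_bp, sets,
                                 paste0("chr", seq_len(n_chromosomes)))
}

#' Generate two-bottle preference trials
#'
#' Trial-level preference ratios on the declining half-logistic
#' `f(x) = 0.5 / (1 + (x / ec50)^h)` with additive Gaussian noise, clamped to
#' `[0, 1]`. The default design mirrors a 5-concentration, 6-trial protocol.
#'
#' @param ec50 concentration at which preference falls to 0.25 (uM).
#' @param h Hill coefficient.
#' @param concentrations tested concentrations (uM).
#' @param trials trials per concentration.
#' @param noise_sd standard deviation of the additive noise.
#' @param seed integer RNG seed.
#' @return data.frame with columns `concentration`, `trial`, `ratio`.
#' @export
generate_preference_trials <- function(ec50, h,
                                       concentrations = c(1, 10, 100, 250, 1000),
                                       trials = 6L, noise_sd = 0.05,
                                       seed = 1L) {
  stopifnot(ec50 > 0, all(concentrations > 0), trials >= 1L, noise_sd >= 0)
  set.seed(seed)
  grid <- expand.grid(trial = seq_len(trials), concentration = concentrations)
  f <- 0.5 / (1 + (grid$concentration / ec50)^h)
  ratio <- pmin(pmax(f + stats::rnorm(nrow(grid), 0, noise_sd), 0), 1)
  data.frame(concentration = grid$concentration, trial = grid$trial,
             ratio = ratio)
}

#' Generate calcium-imaging titration replicates
#'
#' Replicate responses on the increasing four-parameter logistic
#' `f(x) = i_min + (i_max - i_min) / (1 + (ec50 / x)^h)` with additive
#' Gaussian noise; three replicates per concentration by default.
#'
#' @param i_min,i_max lower and upper response asymptotes (delta F / F).
#' @param ec50 half-maximal concentration (uM).
#' @param h Hill coefficient.
#' @param concentrations tested concentrations (uM).
#' @param replicates replicate measurements per concentration.
#' @param noise_sd standard deviation of the additive noise.
#' @param seed integer RNG seed.
#' @return data.frame with columns `concentration`, `replicate`, `response`.
#' @export
generate_titration_curves <- function(i_min, i_max, ec50, h,
                                      concentrations = 10^seq(-1, 3, by = 0.5),
                                      replicates = 3L, noise_sd = 0,
                                      seed = 1L) {
  stopifnot(ec50 > 0, all(concentrations > 0), replicates >= 1L)
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(replicates),
                      concentration = concentrations)
  f <- i_min + (i_max - i_min) / (1 + (ec50 / grid$concentration)^h)
  data.frame(concentration = grid$concentration, replicate = grid$replicate,
             response = f + stats::rnorm(nrow(grid), 0, noise_sd))
}
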