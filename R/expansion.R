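# Forward Wright-Fisher simulation of a new neutral allele expanding in a
# focal deme with emigration: first-passage times to a target frequency and
# the probability that no copy ever emigrates before the target is reached
# ("allele privacy").

#' Configuration for the allele-expansion simulator
#'
#' @param N diploid effective population size of the focal deme.
#' @param q_target frequency threshold in `[1/(2N), 1]`.
#' @param nm migration parameter Nm (expected emigrant chromosomes per
#'   generation at frequency 1/2 is `nm`); per-chromosome emigration
#'   probability is `m = nm / N`.
#' @param replicates minimum number of successful (target-reaching)
#'   replicates to collect; lost replicates count as attempts and are
#'   reported but not rerun.
#' @param seed integer RNG seed.
#' @param max_generations safety cap per replicate (default `100 * N`);
#'   replicates hitting the cap are censored and excluded with a warning.
#' @return an `expansion_config` list.
#' @export
expansion_config <- function(N, q_target, nm = 0, replicates = 1000L,
                             seed = 1L, max_generations = 100L * N) {
  stopifnot(N >= 1L, nm >= 0, replicates >= 1L)
  if (q_target < 1 / (2 * N) || q_target > 1)
    stop("q_target must lie in [1/(2N), 1]")
  structure(list(N = as.integer(N), q_target = q_target, nm = nm,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 max_generations = as.integer(max_generations)),
            class = "expansion_config")
}

#' Simulate one expansion replicate
#'
#' The allele starts as a single copy among 2N chromosomes. Each generation,
#' (i) every allele copy independently emigrates with probability
#' `m = nm / N` and is replaced by a non-carrier immigrant, then (ii) the
#' next generation is drawn by binomial Wright-Fisher sampling of 2N
#' chromosomes at the post-migration frequency. The replicate terminates at
#' loss, on first reaching `q_target`, or at the generation cap.
#'
#' @param config an [expansion_config()]. The caller seeds the RNG; this
#'   function draws from the current RNG state.
#' @return list with `reached` (logical), `generations` (first-passage
#'   generation, `NA` if not reached), `emigrated` (any emigrant copy before
#'   termination) and `censored`.
#' @export
simulate_expansion_replicate <- function(config) {
  two_n <- 2L * config$N
  thr <- ceiling(config$q_target * two_n - 1e-9)
  m <- config$nm / config$N
  copies <- 1L
  emigrated <- FALSE
  gen <- 0L
  if (copies >= thr)
    return(list(reached = TRUE, generations = 0L, emigrated = FALSE,
                censored = FALSE))
  while (gen < config$max_generations) {
    gen <- gen + 1L
    if (m > 0) {
      e <- stats::rbinom(1L, copies, m)
      if (e > 0L) {
        emigrated <- TRUE
        copies <- copies - e
      }
    }
    copies <- stats::rbinom(1L, two_n, copies / two_n)
    if (copies >= thr)
      return(list(reached = TRUE, generations = gen, emigrated = emigrated,
                  censored = FALSE))
    if (copies == 0L)
      return(list(reached = FALSE, generations = NA_integer_,
                  emigrated = emigrated, censored = FALSE))
  }
  list(reached = FALSE, generations = NA_integer_, emigrated = emigrated,
       censored = TRUE)
}

#' Run the expansion simulation to a fixed number of successes
#'
#' Runs batched, vectorized replicates of [simulate_expansion_replicate()]
#' until `config$replicates` successful (target-reaching) trajectories are
#' collected, and summarizes first-passage times and allele privacy.
#' Conditioning is on reaching the target: lost replicates are counted as
#' attempts only.
#'
#' @param config an [expansion_config()].
#' @param batch internal vectorization width (result-invariant given the
#'   seed only through the summary distribution; fixed default keeps runs
#'   reproducible).
#' @return an `expansion_result` list: `successes`,
#'   `first_passage_generations`, `privacy_retained` (per success),
#'   `privacy_probability`, `privacy_se`, `mean_time_in_N_units`,
#'   `se_time_in_N_units`, `attempts`, `censored`.
#' @export
simulate_expansion <- function(config, batch = 20000L) {
  stopifnot(inherits(config, "expansion_config"))
  set.seed(config$seed)
  two_n <- 2L * config$N
  thr <- ceiling(config$q_target * two_n - 1e-9)
  m <- config$nm / config$N
  succ_gen <- integer(0)
  succ_priv <- logical(0)
  attempts <- 0L
  censored <- 0L
  if (thr <= 1L) {
    # already at or above the target at the initial copy
    succ_gen <- rep(0L, config$replicates)
    succ_priv <- rep(TRUE, config$replicates)
    attempts <- config$replicates
  }
  while (length(succ_gen) < config$replicates) {
    copies <- rep(1L, batch)
    emig <- rep(FALSE, batch)
    attempts <- attempts + batch
    gen <- 0L
    while (length(copies) > 0L) {
      gen <- gen + 1L
      if (gen > config$max_generations) {
        censored <- censored + length(copies)
        break
      }
      if (m > 0) {
        e <- stats::rbinom(length(copies), copies, m)
        emig <- emig | (e > 0L)
        copies <- copies - e
      }
      copies <- stats::rbinom(length(copies), two_n, copies / two_n)
      done_s <- copies >= thr
      if (any(done_s)) {
        succ_gen <- c(succ_gen, rep.int(gen, sum(done_s)))
        succ_priv <- c(succ_priv, !emig[done_s])
      }
      keep <- !done_s & copies > 0L
      copies <- copies[keep]
      emig <- emig[keep]
    }
  }
  if (censored > 0L)
    warning(censored, " replicate(s) hit max_generations and were censored")
  # all successes from completed batches are kept (possibly more than
  # requested), so successes / attempts is an unbiased success-probability
  # estimate
  p <- mean(succ_priv)
  t_mean <- mean(succ_gen) / config$N
  structure(list(
    successes = length(succ_gen),
    first_passage_generations = succ_gen,
    privacy_retained = succ_priv,
    privacy_probability = p,
    privacy_se = sqrt(p * (1 - p) / length(succ_priv)),
    mean_time_in_N_units = t_mean,
    se_time_in_N_units = stats::sd(succ_gen) / config$N / sqrt(length(succ_gen)),
    attempts = attempts,
    censored = censored,
    config = config), class = "expansion_result")
}

#' @export
print.expansion_result <- function(x, ...) {
  cat("expansion_result: N =", x$config$N, " q* =", x$config$q_target,
      " Nm =", x$config$nm, "\n")
  cat("  ", x$successes, " successes / ", x$attempts, " attempts\n", sep = "")
  cat(sprintf("  mean first-passage time: %.3f N generations (SE %.3f)\n",
              x$mean_time_in_N_units, x$se_time_in_N_units))
  cat(sprintf("  privacy probability: %.4f (SE %.4f)\n",
              x$privacy_probability, x$privacy_se))
  invisible(x)
}

#' Mean conditional first-passage time without migration
#'
#' Convenience wrapper: runs [simulate_expansion()] with `nm = 0` and returns
#' the mean first-passage time to `q_target` in units of N generations, with
#' its standard error, conditional on the allele reaching the target.
#'
#' @param config an [expansion_config()] with `nm = 0`.
#' @return list with `mean_time_in_N_units`, `se`, `successes`, `attempts`.
#' @export
estimate_first_passage_time <- function(config) {
  if (config$nm != 0)
    stop("first-passage estimation is defined for the no-migration model; set nm = 0")
  res <- simulate_expansion(config)
  if (res$successes == 0L) stop("no replicate reached the target frequency")
  list(mean_time_in_N_units = res$mean_time_in_N_units,
       se = res$se_time_in_N_units,
       successes = res$successes, attempts = res$attempts)
}

#' Probability that the allele stays private during its expansion
#'
#' Fraction of successful (target-reaching) replicates in which no allele
#' copy emigrated before the target frequency was first reached, with its
#' binomial standard error. Monotone non-increasing in `nm`.
#'
#' @param config an [expansion_config()].
#' @return list with `privacy_probability`, `se`, `successes`, `attempts`.
#' @export
estimate_privacy_probability <- function(config) {
  res <- simulate_expansion(config)
  if (res$successes == 0L) stop("no replicate reached the target frequency")
  list(privacy_probability = res$privacy_probability, se = res$privacy_se,
       successes = res$successes, attempts = res$attempts)
}

#' Diffusion-limit expected first-passage time
#'
#' Closed-form limit (initial frequency tending to 0) of the expected
#' first-passage time of a neutral Wright-Fisher diffusion to frequency `q`,
#' conditional on reaching it: `(4/q) * ((1 - q) * log(1 - q) + q)` in units
#' of N generations. Finite-N simulations exceed this value slightly.
#'
#' @param q_target target frequency in (0, 1).
#' @return expected time in N-generation units.
#' @export
#' @examples
#' diffusion_expected_time(0.29)  # ~0.646
diffusion_expected_time <- function(q_target) {
  if (any(q_target <= 0 | q_target >= 1))
    stop("q_target must lie strictly between 0 and 1")
  (4 / q_target) * ((1 - q_target) * log(1 - q_target) + q_target)
}

#' Convert a time in N-generation units to years
#'
#' @param time_in_N_units time expressed in units of N generations.
#' @param N effective population size.
#' @param generation_time generation time in years.
#' @return time in years (`time_in_N_units * N * generation_time`).
#' @export
#' @examples
#' generations_to_years(0.69, 20000, 6)  # 82800
generations_to_years <- function(time_in_N_units, N, generation_time) {
  stopifnot(time_in_N_units >= 0, N > 0, generation_time > 0)
  time_in_N_units * N * generation_time
}
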