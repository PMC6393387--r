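# Raw chain draw used by all simulator entry points. Genotype is
# Binomial(2, maf) under Hardy-Weinberg equilibrium; errors are independent
# zero-mean Gaussians with the model's error variances. An `error_rng` hook
# (function(n, sd) -> numeric) allows non-Gaussian robustness experiments;
# the analytic theory assumes the Gaussian default.
sim_chain_raw <- function(model, n, error_rng = NULL) {
  sd_e <- sqrt(model$error_var)
  rng <- if (is.null(error_rng)) function(n, sd) rnorm(n, sd = sd) else error_rng
  x1 <- rbinom(n, 2L, model$maf)
  x2 <- model$beta[1] * x1 + rng(n, sd_e[1])
  x3 <- model$beta[2] * x2 + rng(n, sd_e[2])
  y <- model$beta[3] * x3 + rng(n, sd_e[3])
  list(x1 = x1, x2 = x2, x3 = x3, y = y)
}

rep_seed <- function(seed, i) {
  (as.integer(seed) + i - 1L) %% 2147483629L
}

#' Simulate a random-sampling cohort under the causal chain
#'
#' Draws `n` independent individuals from the chain model: genotype
#' Binomial(2, `maf`) under Hardy-Weinberg equilibrium, then RNA, protein and
#' trait by the structural equations with independent Gaussian errors.
#' Identical seeds give identical datasets.
#'
#' @param model A [chain_model()].
#' @param n Number of individuals.
#' @param seed Integer seed; `NULL` leaves the random-number state untouched.
#' @param error_rng Optional error generator `function(n, sd)` replacing the
#'   Gaussian default (simulator-only extension point; the analytic power
#'   theory assumes Gaussian errors).
#' @return A tibble with columns `sample_id`, `genotype`, `rna`, `prt`,
#'   `trait`.
#' @examples
#' simulate_cohort(chain_model(h2 = 0.01), n = 5, seed = 1)
#' @export
simulate_cohort <- function(model, n, seed = NULL, error_rng = NULL) {
  stopifnot(inherits(model, "chain_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop_domain("`n` must be a positive integer.")
  }
  if (!is.null(seed)) set.seed(seed)
  d <- sim_chain_raw(model, n, error_rng)
  tibble(
    sample_id = seq_len(n),
    genotype = d$x1, rna = d$x2, prt = d$x3, trait = d$y
  )
}

#' Simulate an extreme-phenotype sample under the causal chain
#'
#' Simulates a pool of `ceiling(n_selected / (2 * trunc_alpha))` individuals,
#' ranks them by trait, and retains the `n_selected / 2` most extreme
#' individuals from each tail, labelled `"upper"` and `"lower"`. With
#' `keep_pool = TRUE` the whole pool is returned with unselected individuals
#' labelled `"none"`.
#'
#' @inheritParams simulate_cohort
#' @param n_selected Even total number of retained individuals.
#' @param trunc_alpha Per-tail truncation fraction in (0, 0.5].
#' @param keep_pool Return the full simulated pool rather than only the
#'   selected individuals.
#' @return A tibble with columns `sample_id`, `genotype`, `rna`, `prt`,
#'   `trait`, `tail_label`.
#' @examples
#' simulate_eps(chain_model(h2 = 0.01), n_selected = 20, seed = 1)
#' @export
simulate_eps <- function(model, n_selected, trunc_alpha = 0.2, seed = NULL,
                         keep_pool = FALSE, error_rng = NULL) {
  stopifnot(inherits(model, "chain_model"))
  check_alpha(trunc_alpha)
  if (!is.numeric(n_selected) || length(n_selected) != 1L || n_selected < 4 ||
      n_selected != round(n_selected) || n_selected %% 2 != 0) {
    stop_domain("`n_selected` must be an even integer of at least 4.")
  }
  if (!is.null(seed)) set.seed(seed)
  k <- n_selected / 2
  pool_n <- max(ceiling(n_selected / (2 * trunc_alpha)), n_selected)
  d <- sim_chain_raw(model, pool_n, error_rng)
  ord <- order(d$y) # continuous trait: ties have probability zero
  label <- rep("none", pool_n)
  label[ord[seq_len(k)]] <- "lower"
  label[ord[seq(pool_n - k + 1, pool_n)]] <- "upper"
  out <- tibble(
    sample_id = seq_len(pool_n),
    genotype = d$x1, rna = d$x2, prt = d$x3, trait = d$y,
    tail_label = label
  )
  if (keep_pool) out else out[out$tail_label != "none", ]
}

#' Empirical power of the level-specific tests by Monte Carlo
#'
#' For each of `reps` seeded replicates, generates data under the chain model
#' and sampling scheme, applies the level-specific association test (slope
#' t-test under `"srs"`, pooled two-sample t-test between trait tails under
#' `"eps"`) at `sig_level`, and reports the rejection frequency with its
#' binomial Monte-Carlo standard error. This is the resampling cross-check
#' for the analytic [chain_power()]. Replicate r uses the derived seed
#' `seed + r - 1`, so results are reproducible and independent of chunking.
#'
#' @inheritParams chain_power
#' @param reps Number of Monte-Carlo replicates (>= 100).
#' @param seed Integer base seed.
#' @param scheme `"srs"` or `"eps"`.
#' @param n Total sample size per replicate (even under `"eps"`).
#' @return A tibble with one row per level: `level`, `scheme`, `n`, `reps`,
#'   `rejections`, `power_hat`, `mc_se`.
#' @examples
#' \donttest{
#' m <- chain_model(h2 = 0.01)
#' empirical_power(m, scheme = "srs", n = 200, reps = 200, seed = 1,
#'                 sig_level = 0.05)
#' }
#' @export
empirical_power <- function(model, scheme = c("srs", "eps"), n, reps,
                            seed = 1L, sig_level = 2.5e-6, trunc_alpha = 0.2,
                            sides = 2, error_rng = NULL) {
  stopifnot(inherits(model, "chain_model"))
  scheme <- match.arg(scheme)
  sides <- check_sides(sides)
  check_sig_level(sig_level)
  if (!is.numeric(reps) || length(reps) != 1L || reps < 100) {
    stop_domain("`reps` must be at least 100.")
  }
  check_n(n, even = scheme == "eps")
  df <- n - 2L
  # constant critical value across replicates
  tc <- if (sides == 2L) qt(1 - sig_level / 2, df) else qt(1 - sig_level, df)
  rej <- c(snp = 0L, rna = 0L, prt = 0L)
  k <- n / 2
  pool_n <- max(ceiling(n / (2 * trunc_alpha)), n)
  for (r in seq_len(reps)) {
    set.seed(rep_seed(seed, r))
    if (scheme == "srs") {
      d <- sim_chain_raw(model, n, error_rng)
      stats <- c(
        snp = slope_t_core(d$x1, d$y)$t_stat,
        rna = slope_t_core(d$x2, d$y)$t_stat,
        prt = slope_t_core(d$x3, d$y)$t_stat
      )
    } else {
      d <- sim_chain_raw(model, pool_n, error_rng)
      ord <- order(d$y)
      lo <- ord[seq_len(k)]
      up <- ord[seq(pool_n - k + 1, pool_n)]
      stats <- c(
        snp = two_sample_t_core(d$x1[up], d$x1[lo])$t_stat,
        rna = two_sample_t_core(d$x2[up], d$x2[lo])$t_stat,
        prt = two_sample_t_core(d$x3[up], d$x3[lo])$t_stat
      )
    }
    hit <- if (sides == 2L) abs(stats) > tc else stats > tc
    rej <- rej + hit
  }
  power_hat <- rej / reps
  tibble(
    level = names(rej),
    scheme = scheme,
    n = as.integer(n),
    reps = as.integer(reps),
    rejections = as.integer(rej),
    power_hat = unname(power_hat),
    mc_se = unname(sqrt(power_hat * (1 - power_hat) / reps))
  )
}
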