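#' Noncentrality parameter of the slope t-test under simple random sampling
#'
#' For a slope test of the trait on a level with squared population
#' correlation `rho_sq`, based on `n` randomly sampled individuals, the
#' t statistic is approximately noncentral t with `n - 2` degrees of freedom
#' and noncentrality \eqn{\delta = \sqrt{n}\,\rho / \sqrt{1 - \rho^2}}.
#'
#' @param rho_sq Squared level-trait correlation(s) in \[0, 1).
#' @param n Total sample size(s), at least 4.
#' @return Noncentrality parameter(s), non-negative.
#' @examples
#' srs_ncp(0.01, 3055)
#' @export
srs_ncp <- function(rho_sq, n) {
  check_rho_sq(rho_sq)
  check_n(n, even = FALSE)
  sqrt(n) * sqrt(rho_sq) / sqrt(1 - rho_sq)
}

#' Noncentrality parameter of the two-sample t-test under extreme sampling
#'
#' Under extreme phenotype sampling, `n/2` individuals are drawn from each of
#' the upper and lower 100`trunc_alpha`% trait tails and the level variable is
#' compared between tails by a pooled two-sample t-test. With between-tail
#' mean separation \eqn{2\rho\lambda(\alpha)} and within-tail standard
#' deviation \eqn{\sigma_{\mathrm{tail}} =
#' \sqrt{1 - \rho^2(1 - \mathrm{tail\_var}(\alpha))}}, the noncentrality is
#' \eqn{\delta = \rho\,\lambda(\alpha)\,\sqrt{n} / \sigma_{\mathrm{tail}}}.
#'
#' @inheritParams srs_ncp
#' @param n Total (two-tail) sample size(s); must be even and at least 4.
#' @param trunc_alpha Per-tail truncation fraction in (0, 0.5].
#' @param shrink If `TRUE` (default) the within-tail variance shrinkage
#'   \eqn{\sigma_{\mathrm{tail}}} is applied; `FALSE` uses unit within-tail
#'   standard deviation. The two variants bracket plausible selection-theory
#'   approximations; the shrinkage version matches the Monte-Carlo simulator.
#' @return Noncentrality parameter(s), non-negative.
#' @examples
#' eps_ncp(0.019578, 796, 0.2)
#' @export
eps_ncp <- function(rho_sq, n, trunc_alpha = 0.2, shrink = TRUE) {
  check_rho_sq(rho_sq)
  check_n(n, even = TRUE)
  check_alpha(trunc_alpha)
  sigma_tail <- if (shrink) {
    sqrt(1 - rho_sq * (1 - tail_var_(trunc_alpha)))
  } else {
    1
  }
  sqrt(rho_sq) * tail_lambda(trunc_alpha) * sqrt(n) / sigma_tail
}

check_rho_sq <- function(rho_sq) {
  if (!is.numeric(rho_sq) || anyNA(rho_sq) || any(rho_sq < 0) ||
      any(rho_sq >= 1)) {
    stop_domain("`rho_sq` must be squared correlations in [0, 1).")
  }
  invisible(rho_sq)
}

check_n <- function(n, even = FALSE) {
  if (!is.numeric(n) || anyNA(n) || any(n < 4) || any(n != round(n))) {
    stop_domain("`n` must be integer sample sizes of at least 4.")
  }
  if (even && any(n %% 2 != 0)) {
    stop_domain("`n` must be even under extreme phenotype sampling (n/2 per tail).")
  }
  invisible(n)
}

#' Power of a t-test from its noncentrality parameter
#'
#' Probability that a noncentral t variable with `df` degrees of freedom and
#' noncentrality `ncp` falls beyond the central-t critical value at
#' `sig_level`. Two-sided power counts both rejection tails; at `ncp = 0` the
#' power equals `sig_level` exactly (the test size).
#'
#' @param ncp Noncentrality parameter(s).
#' @param df Residual degrees of freedom, at least 1.
#' @param sig_level Nominal significance level in (0, 1); the default
#'   2.5e-6 is a Bonferroni-style genome-wide level (0.05 over ~20,000
#'   protein-coding genes).
#' @param sides 1 or 2 (default 2, two-sided).
#' @param normal_approx If `TRUE`, use the large-sample normal approximation
#'   \eqn{\Phi(\delta - z_{1-\alpha/2}) + \Phi(-\delta - z_{1-\alpha/2})}
#'   instead of the noncentral t distribution.
#' @return Power value(s) in (0, 1).
#' @examples
#' power_from_ncp(5.55, df = 3053)
#' @export
power_from_ncp <- function(ncp, df, sig_level = 2.5e-6, sides = 2,
                           normal_approx = FALSE) {
  check_sig_level(sig_level)
  sides <- check_sides(sides)
  if (!is.numeric(df) || anyNA(df) || any(df < 1)) {
    stop_domain("`df` must be at least 1.")
  }
  if (normal_approx) {
    if (sides == 2L) {
      zc <- qnorm(1 - sig_level / 2)
      out <- pnorm(ncp - zc) + pnorm(-ncp - zc)
    } else {
      zc <- qnorm(1 - sig_level)
      out <- pnorm(ncp - zc)
    }
  } else if (sides == 2L) {
    tc <- qt(1 - sig_level / 2, df)
    out <- pt(tc, df, ncp = ncp, lower.tail = FALSE) + pt(-tc, df, ncp = ncp)
  } else {
    tc <- qt(1 - sig_level, df)
    out <- pt(tc, df, ncp = ncp, lower.tail = FALSE)
  }
  # the noncentral algorithm at ncp = 0 is the size by construction
  out[ncp == 0] <- sig_level
  out
}

level_rho_sq <- function(model, level) {
  unname(model$level_cor[level])
}

chain_levels <- c("snp", "rna", "prt")

#' Analytic power of the level-specific association tests
#'
#' Computes, for each requested omics level and sampling scheme, the analytic
#' power of the level-trait association test: the slope t-test under simple
#' random sampling (`"srs"`) or the pooled two-sample t-test between trait
#' tails under extreme phenotype sampling (`"eps"`). Power is evaluated from
#' the noncentral t distribution with `n - 2` degrees of freedom (see
#' [srs_ncp()], [eps_ncp()], [power_from_ncp()]).
#'
#' @param model A [chain_model()].
#' @param n Total sample size(s); even values are required for `"eps"`.
#' @param scheme Sampling scheme(s): any of `"srs"`, `"eps"`.
#' @param level Omics level(s): any of `"snp"`, `"rna"`, `"prt"`.
#' @inheritParams power_from_ncp
#' @inheritParams eps_ncp
#' @return A tibble with columns `scheme`, `level`, `n`, `rho_sq`, `ncp`,
#'   `df`, `power`, one row per scheme x level x n combination.
#' @examples
#' chain_power(chain_model(h2 = 0.01), n = 200)
#' @export
chain_power <- function(model, n, scheme = c("srs", "eps"),
                        level = c("snp", "rna", "prt"),
                        sig_level = 2.5e-6, trunc_alpha = 0.2, sides = 2,
                        shrink = TRUE, normal_approx = FALSE) {
  stopifnot(inherits(model, "chain_model"))
  scheme <- match.arg(scheme, several.ok = TRUE)
  level <- match.arg(level, several.ok = TRUE)
  grid <- tidyr::expand_grid(scheme = scheme, level = level, n = n)
  pmap_dfr(grid, function(scheme, level, n) {
    rho_sq <- level_rho_sq(model, level)
    ncp <- if (scheme == "srs") {
      srs_ncp(rho_sq, n)
    } else {
      eps_ncp(rho_sq, n, trunc_alpha, shrink)
    }
    tibble(
      scheme = scheme, level = level, n = as.integer(n), rho_sq = rho_sq,
      ncp = ncp, df = as.integer(n - 2),
      power = power_from_ncp(ncp, n - 2, sig_level, sides, normal_approx)
    )
  })
}

#' Minimal sample size reaching a target power
#'
#' Inverts [chain_power()] over the integer sample-size grid: the smallest
#' admissible total `n` (smallest even `n` under extreme phenotype sampling)
#' whose analytic power reaches `target_power`. Power is strictly increasing
#' in `n`, so the search brackets the target by doubling and finishes by
#' integer bisection; the result satisfies power(`n_required`) >=
#' `target_power` > power at the previous admissible `n`.
#'
#' @inheritParams chain_power
#' @param target_power Target power in (`sig_level`, 1); default 0.80.
#' @return A tibble with columns `scheme`, `level`, `rho_sq`, `target_power`,
#'   `n_required`, `achieved_power`.
#' @examples
#' chain_sample_size(chain_model(h2 = 0.01), scheme = "srs", level = "snp")
#' @export
chain_sample_size <- function(model, target_power = 0.8,
                              scheme = c("srs", "eps"),
                              level = c("snp", "rna", "prt"),
                              sig_level = 2.5e-6, trunc_alpha = 0.2, sides = 2,
                              shrink = TRUE, normal_approx = FALSE) {
  stopifnot(inherits(model, "chain_model"))
  scheme <- match.arg(scheme, several.ok = TRUE)
  level <- match.arg(level, several.ok = TRUE)
  check_sig_level(sig_level)
  if (!is.numeric(target_power) || length(target_power) != 1L ||
      target_power <= sig_level || target_power >= 1) {
    stop_domain("`target_power` must lie in (sig_level, 1).")
  }
  grid <- tidyr::expand_grid(scheme = scheme, level = level)
  pmap_dfr(grid, function(scheme, level) {
    rho_sq <- level_rho_sq(model, level)
    if (rho_sq <= 0) {
      stop_domain(sprintf(
        "Target power is unattainable: the %s-trait correlation is 0.",
        toupper(level)
      ))
    }
    pow_at <- function(n) {
      ncp <- if (scheme == "srs") {
        srs_ncp(rho_sq, n)
      } else {
        eps_ncp(rho_sq, n, trunc_alpha, shrink)
      }
      power_from_ncp(ncp, n - 2, sig_level, sides, normal_approx)
    }
    step <- if (scheme == "eps") 2L else 1L
    lo <- 4L
    hi <- 16L
    while (pow_at(hi) < target_power) {
      lo <- hi
      hi <- hi * 2L
      if (hi > 2^31 - 2) {
        stop_domain("Sample-size search exceeded the integer range.")
      }
    }
    if (pow_at(lo) >= target_power) hi <- lo
    while (hi - lo > step) {
      mid <- lo + ((hi - lo) %/% (2L * step)) * step
      if (mid <= lo) mid <- lo + step
      if (pow_at(mid) >= target_power) hi <- mid else lo <- mid
    }
    tibble(
      scheme = scheme, level = level, rho_sq = rho_sq,
      target_power = target_power, n_required = as.integer(hi),
      achieved_power = pow_at(hi)
    )
  })
}
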