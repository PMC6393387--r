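# Closed-form cores shared by the user-facing tests and the Monte-Carlo
# simulator (the simulator runs them inside 10^4-replicate loops, so they
# avoid model-frame overhead). Cross-checked against stats::lm and
# stats::t.test in the test suite.

slope_t_core <- function(x, y) {
  n <- length(x)
  xc <- x - mean(x)
  yc <- y - mean(y)
  sxx <- sum(xc^2)
  if (sxx <= 0) {
    stop_domain("`x` is constant; the slope test is undefined.")
  }
  syy <- sum(yc^2)
  sxy <- sum(xc * yc)
  slope <- sxy / sxx
  df <- n - 2L
  if (syy <= 0) {
    return(list(estimate = 0, t_stat = 0, df = df, degenerate = FALSE))
  }
  sse <- syy - slope * sxy
  if (sse <= 1e-12 * syy) {
    return(list(
      estimate = slope, t_stat = sign(slope) * Inf, df = df, degenerate = TRUE
    ))
  }
  se <- sqrt(sse / df / sxx)
  list(estimate = slope, t_stat = slope / se, df = df, degenerate = FALSE)
}

two_sample_t_core <- function(upper, lower, welch = FALSE) {
  n_u <- length(upper)
  n_l <- length(lower)
  diff <- mean(upper) - mean(lower)
  ss_u <- sum((upper - mean(upper))^2)
  ss_l <- sum((lower - mean(lower))^2)
  if (welch) {
    v_u <- ss_u / (n_u - 1) / n_u
    v_l <- ss_l / (n_l - 1) / n_l
    se2 <- v_u + v_l
    df <- se2^2 / (v_u^2 / (n_u - 1) + v_l^2 / (n_l - 1))
  } else {
    df <- n_u + n_l - 2L
    se2 <- (ss_u + ss_l) / df * (1 / n_u + 1 / n_l)
  }
  if (se2 <= 1e-24 * max(diff^2, 1e-300)) {
    if (diff == 0) {
      return(list(estimate = 0, t_stat = 0, df = df, degenerate = FALSE))
    }
    return(list(
      estimate = diff, t_stat = sign(diff) * Inf, df = df, degenerate = TRUE
    ))
  }
  list(estimate = diff, t_stat = diff / sqrt(se2), df = df, degenerate = FALSE)
}

t_p_value <- function(t_stat, df, sides) {
  if (!is.finite(t_stat)) {
    return(0)
  }
  if (sides == 2L) {
    2 * pt(-abs(t_stat), df)
  } else {
    pt(t_stat, df, lower.tail = FALSE)
  }
}

core_to_tibble <- function(core, sides) {
  tibble(
    estimate = core$estimate,
    t_stat = core$t_stat,
    df = core$df,
    p_value = if (core$degenerate) 0 else t_p_value(core$t_stat, core$df, sides),
    degenerate = core$degenerate
  )
}

#' Classical t-test for a regression slope
#'
#' Ordinary least-squares slope of `y` on `x` with its t statistic on
#' `n - 2` residual degrees of freedom; the association test used under
#' simple random sampling. A zero residual variance with a non-zero slope
#' (perfect fit) is reported with `degenerate = TRUE` and `p_value = 0`.
#'
#' @param x Predictor vector (e.g. genotype 0/1/2 or an expression level);
#'   must not be constant.
#' @param y Response vector (the trait), same length as `x`, length >= 3.
#' @param sides 1 (upper-tailed) or 2 (two-sided, default).
#' @return A one-row tibble with columns `estimate`, `t_stat`, `df`,
#'   `p_value`, `degenerate`.
#' @examples
#' slope_t_test(c(0, 1, 2), c(0, 1, 1))
#' @export
slope_t_test <- function(x, y, sides = 2) {
  sides <- check_sides(sides)
  if (length(x) != length(y) || length(x) < 3L) {
    stop_domain("`x` and `y` must have equal length of at least 3.")
  }
  core_to_tibble(slope_t_core(x, y), sides)
}

#' Two-sample t-test between trait tails
#'
#' Pooled-variance two-sample t-test comparing an omics variable between the
#' upper and lower trait tails; the association test used under extreme
#' phenotype sampling. The pooled version keeps the `n - 2` degrees-of-freedom
#' convention assumed by the analytic power engine; a Welch variant is
#' available for data analysis.
#'
#' @param upper,lower Numeric vectors of the variable in each tail, each of
#'   length >= 2.
#' @param sides 1 (upper-tailed, upper minus lower) or 2 (two-sided, default).
#' @param welch Use the Welch (unequal-variance) statistic instead of the
#'   pooled one.
#' @return A one-row tibble with columns `estimate` (mean difference),
#'   `t_stat`, `df`, `p_value`, `degenerate`.
#' @examples
#' two_sample_t_test(c(2, 3), c(0, 1))
#' @export
two_sample_t_test <- function(upper, lower, sides = 2, welch = FALSE) {
  sides <- check_sides(sides)
  if (length(upper) < 2L || length(lower) < 2L) {
    stop_domain("Each group needs at least 2 observations.")
  }
  core_to_tibble(two_sample_t_core(upper, lower, welch), sides)
}

#' Level-specific association tests on a per-sample table
#'
#' Applies the appropriate level-trait association test to each omics level
#' of a per-sample table: under `"srs"`, the slope t-test of the trait on
#' genotype, RNA and protein in turn; under `"eps"`, the pooled two-sample
#' t-test of each level variable between the upper and lower trait tails.
#' Tails are taken from a `tail_label` column (values `"upper"`, `"lower"`;
#' other rows are dropped) when present, otherwise the most extreme
#' `floor(trunc_alpha * n)` samples on each side of the trait distribution
#' are labelled.
#'
#' @param data A data frame with numeric columns `genotype` (values 0/1/2),
#'   `rna`, `prt` and `trait`; extra columns are ignored.
#' @param scheme `"srs"` or `"eps"`.
#' @param trunc_alpha Per-tail fraction used to derive tails under `"eps"`
#'   when `data` has no `tail_label` column.
#' @param sig_level Significance level used for the `reject` column.
#' @param sides 1 or 2 (default 2).
#' @param welch Use Welch two-sample tests under `"eps"`.
#' @return A tibble with one row per level and columns `level`, `scheme`,
#'   `estimate`, `t_stat`, `df`, `p_value`, `reject`, `degenerate`.
#' @examples
#' cohort <- simulate_cohort(chain_model(h2 = 0.01), n = 500, seed = 1)
#' chain_test(cohort, scheme = "srs", sig_level = 0.05)
#' @export
chain_test <- function(data, scheme = c("srs", "eps"), trunc_alpha = 0.2,
                       sig_level = 2.5e-6, sides = 2, welch = FALSE) {
  scheme <- match.arg(scheme)
  sides <- check_sides(sides)
  check_sig_level(sig_level)
  needed <- c("genotype", "rna", "prt", "trait")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop_usage(sprintf(
      "`data` is missing required column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (!all(data$genotype %in% c(0, 1, 2))) {
    stop_domain("`genotype` must contain only the values 0, 1 and 2.")
  }
  level_cols <- c(snp = "genotype", rna = "rna", prt = "prt")
  if (scheme == "srs") {
    res <- map_dfr(names(level_cols), function(lv) {
      mutate(
        core_to_tibble(slope_t_core(data[[level_cols[lv]]], data$trait), sides),
        level = lv, .before = 1
      )
    })
  } else {
    check_alpha(trunc_alpha)
    if (!is.null(data[["tail_label"]])) {
      up <- data$tail_label == "upper"
      lo <- data$tail_label == "lower"
    } else {
      k <- floor(trunc_alpha * nrow(data))
      if (k < 2) {
        stop_domain("Too few samples per tail; increase `trunc_alpha` or n.")
      }
      ord <- order(data$trait)
      lo <- up <- rep(FALSE, nrow(data))
      lo[ord[seq_len(k)]] <- TRUE
      up[ord[seq(nrow(data) - k + 1, nrow(data))]] <- TRUE
    }
    if (sum(up) < 2 || sum(lo) < 2) {
      stop_domain("Each tail needs at least 2 samples.")
    }
    res <- map_dfr(names(level_cols), function(lv) {
      v <- data[[level_cols[lv]]]
      mutate(
        core_to_tibble(two_sample_t_core(v[up], v[lo], welch), sides),
        level = lv, .before = 1
      )
    })
  }
  mutate(res,
    scheme = scheme, .after = "level"
  ) |>
    mutate(reject = .data$p_value < sig_level, .after = "p_value")
}
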