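#' Power and sample-size curves across heritability or sample-size grids
#'
#' Tabulates the six analytic curves (two sampling schemes x three omics
#' levels) in one of three modes:
#' \describe{
#'   \item{`"power_vs_h2"`}{power at fixed total `n` across a heritability
#'     grid; each grid point rescales the anchor's mediate correlations by a
#'     common cube-root factor ([scale_to_heritability()]).}
#'   \item{`"power_vs_n"`}{power of a fixed model across a sample-size grid.}
#'   \item{`"n_vs_h2"`}{minimal sample size reaching `target_power` across a
#'     heritability grid.}
#' }
#'
#' @param model Anchor [chain_model()]; its mediate correlations define the
#'   heritability path, its `maf` and error variances are kept fixed.
#' @param mode One of `"power_vs_h2"`, `"power_vs_n"`, `"n_vs_h2"`.
#' @param h2 Heritability grid (modes `"power_vs_h2"`, `"n_vs_h2"`).
#' @param n Total sample size: scalar for `"power_vs_h2"` (default 200), grid
#'   for `"power_vs_n"`. Even values are required for the EPS curves.
#' @param target_power Target power for `"n_vs_h2"` (default 0.80).
#' @inheritParams chain_power
#' @return A tibble of class `chain_power_curve` with columns `scheme`,
#'   `level`, `h2`, `n`, and `power` (or `n_required`, `achieved_power` for
#'   mode `"n_vs_h2"`); the mode is stored in attribute `"mode"`.
#' @examples
#' pc <- power_curve(chain_model(h2 = 0.01), "power_vs_h2",
#'                   h2 = seq(0, 0.025, by = 0.005), n = 200)
#' head(pc)
#' @export
power_curve <- function(model, mode = c("power_vs_h2", "power_vs_n", "n_vs_h2"),
                        h2 = seq(0, 0.025, by = 5e-4),
                        n = 200,
                        target_power = 0.8,
                        scheme = c("srs", "eps"),
                        level = c("snp", "rna", "prt"),
                        sig_level = 2.5e-6, trunc_alpha = 0.2, sides = 2,
                        shrink = TRUE, normal_approx = FALSE) {
  stopifnot(inherits(model, "chain_model"))
  mode <- match.arg(mode)
  scheme <- match.arg(scheme, several.ok = TRUE)
  level <- match.arg(level, several.ok = TRUE)
  model_at <- function(h2x) {
    if (h2x == model$h2) {
      model
    } else {
      chain_model(
        maf = model$maf, h2 = h2x, error_var = model$error_var,
        anchor = model$r_squared
      )
    }
  }
  out <- switch(
    mode,
    power_vs_h2 = map_dfr(h2, function(h2x) {
      mutate(
        chain_power(model_at(h2x), n = n, scheme = scheme, level = level,
                    sig_level = sig_level, trunc_alpha = trunc_alpha,
                    sides = sides, shrink = shrink,
                    normal_approx = normal_approx),
        h2 = h2x, .before = "n"
      )
    }),
    power_vs_n = mutate(
      chain_power(model, n = n, scheme = scheme, level = level,
                  sig_level = sig_level, trunc_alpha = trunc_alpha,
                  sides = sides, shrink = shrink,
                  normal_approx = normal_approx),
      h2 = model$h2, .before = "n"
    ),
    n_vs_h2 = map_dfr(h2, function(h2x) {
      mutate(
        chain_sample_size(model_at(h2x), target_power = target_power,
                          scheme = scheme, level = level,
                          sig_level = sig_level, trunc_alpha = trunc_alpha,
                          sides = sides, shrink = shrink,
                          normal_approx = normal_approx),
        h2 = h2x, .before = "target_power"
      )
    })
  )
  out <- arrange(out, .data$scheme, .data$level)
  structure(out, mode = mode, class = c("chain_power_curve", class(out)))
}

#' Plot power or sample-size curves
#'
#' Draws the curve table produced by [power_curve()] as a ggplot: one colour
#' per sampling scheme, one linetype per omics level, with a log-scaled
#' vertical axis for sample-size curves.
#'
#' @param object A [power_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chain_power_curve <- function(object, ...) {
  mode <- attr(object, "mode")
  df <- as_tibble(object)
  df$level <- factor(df$level, levels = chain_levels,
                     labels = toupper(chain_levels))
  df$scheme <- toupper(df$scheme)
  if (mode == "n_vs_h2") {
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$h2, y = .data$n_required,
      colour = .data$scheme, linetype = .data$level
    )) +
      ggplot2::scale_y_log10() +
      ggplot2::labs(
        x = "SNP heritability", y = "total sample size for target power"
      )
  } else {
    xvar <- if (mode == "power_vs_h2") "h2" else "n"
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data[[xvar]], y = .data$power,
      colour = .data$scheme, linetype = .data$level
    )) +
      ggplot2::labs(
        x = if (mode == "power_vs_h2") "SNP heritability" else "total sample size",
        y = "power"
      )
  }
  p + ggplot2::geom_line() + ggplot2::theme_minimal() +
    ggplot2::labs(colour = "sampling", linetype = "level")
}

#' @export
plot.chain_power_curve <- function(x, ...) {
  print(autoplot(x, ...))
  invisible(x)
}

#' Sample sizes required at reference heritability levels
#'
#' Tabulates, for each sampling scheme and omics level, the minimal total
#' sample size achieving `target_power` at each heritability in `h2`,
#' using the anchored cube-root heritability path. With the defaults this
#' reproduces the package's reference sample-size table (heritability 0.1%
#' and 1.0%, power 80%, significance 2.5e-6, truncation 0.2).
#'
#' @inheritParams power_curve
#' @return A tibble with columns `h2`, `scheme`, `level`, `rho_sq`,
#'   `target_power`, `n_required`, `achieved_power`.
#' @examples
#' \donttest{
#' sample_size_table()
#' }
#' @export
sample_size_table <- function(model = chain_model(beta = c(0.5744, 0.7183, 0.4564)),
                              h2 = c(0.001, 0.01),
                              target_power = 0.8,
                              sig_level = 2.5e-6, trunc_alpha = 0.2,
                              sides = 2, shrink = TRUE,
                              normal_approx = FALSE) {
  map_dfr(h2, function(h2x) {
    m <- chain_model(maf = model$maf, h2 = h2x, error_var = model$error_var,
                     anchor = model$r_squared)
    mutate(
      chain_sample_size(m, target_power = target_power,
                        sig_level = sig_level, trunc_alpha = trunc_alpha,
                        sides = sides, shrink = shrink,
                        normal_approx = normal_approx),
      h2 = h2x, .before = 1
    )
  })
}
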