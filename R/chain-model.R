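#' Variance propagation along the causal chain
#'
#' The chain is a linear structural model
#' \deqn{X_2 = \beta_1 X_1 + e_2, \quad X_3 = \beta_2 X_2 + e_3, \quad
#'       Y = \beta_3 X_3 + e_4,}
#' where \eqn{X_1} is the additive genotype score (0/1/2 copies of the minor
#' allele under Hardy-Weinberg equilibrium, so \eqn{\sigma^2_{X_1} = 2p(1-p)}),
#' \eqn{X_2} is RNA expression, \eqn{X_3} protein expression and \eqn{Y} the
#' trait, with mutually independent zero-mean exogenous errors.
#'
#' @param maf Minor allele frequency of the causal SNP, in (0, 0.5].
#' @param beta Numeric vector of the three structural slopes
#'   \eqn{(\beta_1, \beta_2, \beta_3)}.
#' @param error_var Variances of the exogenous errors \eqn{(e_2, e_3, e_4)};
#'   defaults to unit variances.
#'
#' @return A one-row tibble with columns `var_x1`, `var_x2`, `var_x3`, `var_y`.
#' @examples
#' variance_chain(0.25, c(0.5744, 0.7183, 0.4564))
#' @export
variance_chain <- function(maf, beta, error_var = c(1, 1, 1)) {
  v <- unname(variance_chain_(maf, beta, error_var))
  tibble(var_x1 = v[1], var_x2 = v[2], var_x3 = v[3], var_y = v[4])
}

variance_chain_ <- function(maf, beta, error_var = c(1, 1, 1)) {
  check_maf(maf)
  check_error_var(error_var)
  if (!is.numeric(beta) || length(beta) != 3L || anyNA(beta)) {
    stop_domain("`beta` must be three real slopes.")
  }
  var_x1 <- 2 * maf * (1 - maf)
  var_x2 <- beta[1]^2 * var_x1 + error_var[1]
  var_x3 <- beta[2]^2 * var_x2 + error_var[2]
  var_y <- beta[3]^2 * var_x3 + error_var[3]
  c(var_x1 = var_x1, var_x2 = var_x2, var_x3 = var_x3, var_y = var_y)
}

#' Mediate squared correlations and SNP heritability
#'
#' Each consecutive pair of chain levels has squared correlation
#' \eqn{r_k^2 = \beta_k^2 \sigma^2_{X_k} / \sigma^2_{X_{k+1}}}; the
#' heritability of the causal SNP is their product
#' \eqn{h^2 = r_1^2 r_2^2 r_3^2}.
#'
#' @inheritParams variance_chain
#' @return A one-row tibble with columns `r1sq`, `r2sq`, `r3sq`, `h2`.
#' @examples
#' mediate_correlations(0.25, c(0.5744, 0.7183, 0.4564))
#' @export
mediate_correlations <- function(maf, beta, error_var = c(1, 1, 1)) {
  r <- unname(mediate_correlations_(maf, beta, error_var))
  tibble(r1sq = r[1], r2sq = r[2], r3sq = r[3], h2 = prod(r))
}

mediate_correlations_ <- function(maf, beta, error_var = c(1, 1, 1)) {
  v <- variance_chain_(maf, beta, error_var)
  c(
    r1sq = beta[1]^2 * v[["var_x1"]] / v[["var_x2"]],
    r2sq = beta[2]^2 * v[["var_x2"]] / v[["var_x3"]],
    r3sq = beta[3]^2 * v[["var_x3"]] / v[["var_y"]]
  )
}

#' Squared correlation of each omics level with the trait
#'
#' Marginalising the chain gives working models in which the trait regresses
#' on a single level; the squared level-trait correlations are
#' \eqn{h^2 = r_1^2 r_2^2 r_3^2} for the SNP, \eqn{r_2^2 r_3^2} for RNA, and
#' \eqn{r_3^2} for protein. Because every \eqn{r_k^2 < 1}, the more remote a
#' level is from the trait, the smaller its correlation with the trait:
#' `prt >= rna >= snp`, strictly when all mediate correlations lie in (0, 1).
#'
#' @param r_squared Three squared mediate correlations
#'   \eqn{(r_1^2, r_2^2, r_3^2)}, each in \[0, 1), or a [chain_model()].
#'
#' @return A one-row tibble with columns `snp`, `rna`, `prt`.
#' @examples
#' trait_correlations(c(0.1101, 0.3670, 0.2476))
#' @export
trait_correlations <- function(r_squared) {
  r <- trait_correlations_(as_rsq(r_squared))
  tibble(snp = r[["snp"]], rna = r[["rna"]], prt = r[["prt"]])
}

trait_correlations_ <- function(r_squared) {
  check_rsq(r_squared)
  c(
    snp = prod(r_squared),
    rna = r_squared[2] * r_squared[3],
    prt = r_squared[3]
  )
}

as_rsq <- function(r_squared) {
  if (inherits(r_squared, "chain_model")) r_squared$r_squared else r_squared
}

#' Recover chain slopes from target mediate correlations
#'
#' Inverts the forward map of [mediate_correlations()]: given target squared
#' mediate correlations, the minor allele frequency and the exogenous error
#' variances, solves for non-negative slopes by forward recursion,
#' \eqn{\beta_k^2 = r_k^2 \sigma^2_{e_{k+1}} / ((1 - r_k^2)\,\sigma^2_{X_k})}.
#' Slope signs do not affect any squared correlation (hence any power), so
#' the non-negative root is returned.
#'
#' @inheritParams trait_correlations
#' @inheritParams variance_chain
#' @return A one-row tibble with columns `beta1`, `beta2`, `beta3`.
#' @examples
#' params_from_correlations(c(0.1101032, 0.3670052, 0.2475954), maf = 0.25)
#' @export
params_from_correlations <- function(r_squared, maf = 0.25,
                                     error_var = c(1, 1, 1)) {
  b <- unname(params_from_correlations_(as_rsq(r_squared), maf, error_var))
  tibble(beta1 = b[1], beta2 = b[2], beta3 = b[3])
}

params_from_correlations_ <- function(r_squared, maf = 0.25,
                                      error_var = c(1, 1, 1)) {
  check_rsq(r_squared)
  check_maf(maf)
  check_error_var(error_var)
  var_k <- 2 * maf * (1 - maf)
  beta <- numeric(3)
  for (k in 1:3) {
    beta[k] <- sqrt(r_squared[k] * error_var[k] / ((1 - r_squared[k]) * var_k))
    var_k <- beta[k]^2 * var_k + error_var[k]
  }
  c(beta1 = beta[1], beta2 = beta[2], beta3 = beta[3])
}

#' Rescale mediate correlations to a target heritability
#'
#' The heritability-indexed parameter path used by the package's power and
#' sample-size curves: all three squared mediate correlations share a common
#' scale factor, \eqn{r_k^2(h^2) = r_k^2(\mathrm{anchor}) \cdot
#' (h^2 / h^2_{\mathrm{anchor}})^{1/3}}, anchored by default at the reference
#' effect sizes of [chain_anchor()]. The resulting heritability equals
#' `h2_target` exactly.
#'
#' @param r_squared Anchor squared mediate correlations (or a [chain_model()]).
#' @param h2_target Target heritability; must be attainable (every scaled
#'   \eqn{r_k^2} must remain below 1).
#' @return A one-row tibble with columns `r1sq`, `r2sq`, `r3sq`, `h2`.
#' @examples
#' scale_to_heritability(chain_anchor(), 0.001)
#' @export
scale_to_heritability <- function(r_squared, h2_target) {
  r <- unname(scale_to_heritability_(as_rsq(r_squared), h2_target))
  tibble(r1sq = r[1], r2sq = r[2], r3sq = r[3], h2 = prod(r))
}

scale_to_heritability_ <- function(r_squared, h2_target) {
  check_rsq(r_squared)
  if (!is.numeric(h2_target) || length(h2_target) != 1L || is.na(h2_target) ||
      h2_target < 0) {
    stop_domain("`h2_target` must be a single non-negative heritability.")
  }
  if (h2_target == 0) {
    return(c(r1sq = 0, r2sq = 0, r3sq = 0))
  }
  h2_anchor <- prod(r_squared)
  if (h2_anchor <= 0) {
    stop_domain("Anchor heritability is zero; cannot rescale to `h2_target` > 0.")
  }
  scaled <- r_squared * (h2_target / h2_anchor)^(1 / 3)
  if (any(scaled >= 1)) {
    stop_domain(
      "`h2_target` is unattainable: a scaled squared correlation reaches 1."
    )
  }
  c(r1sq = scaled[1], r2sq = scaled[2], r3sq = scaled[3])
}

#' Reference anchor effect sizes
#'
#' The default anchor of the heritability path: the squared mediate
#' correlations implied by slopes (0.5744, 0.7183, 0.4564) at minor allele
#' frequency 0.25 with unit error variances, which place the SNP heritability
#' at 1.0%.
#'
#' @return A numeric vector `(r1sq, r2sq, r3sq)`.
#' @examples
#' prod(chain_anchor()) # ~0.01
#' @export
chain_anchor <- function() {
  mediate_correlations_(0.25, c(0.5744, 0.7183, 0.4564))
}

#' Specify a causal chain model
#'
#' Builds the full parameterisation of the genotype -> RNA -> protein -> trait
#' chain from any one of three inputs: the structural slopes `beta`, the
#' squared mediate correlations `r_squared`, or a target heritability `h2`
#' (placed on the anchored common-scaling path, see
#' [scale_to_heritability()]).
#'
#' @inheritParams variance_chain
#' @param r_squared Optional squared mediate correlations
#'   \eqn{(r_1^2, r_2^2, r_3^2)}; slopes are recovered with
#'   [params_from_correlations()].
#' @param h2 Optional target SNP heritability in \[0, 1).
#' @param anchor Anchor squared mediate correlations for the `h2` path;
#'   defaults to [chain_anchor()].
#'
#' @return An object of class `chain_model`: a list with elements `maf`,
#'   `beta`, `error_var`, `variances`, `r_squared`, `h2` and `level_cor`
#'   (squared level-trait correlations named `snp`, `rna`, `prt`).
#' @examples
#' m <- chain_model(beta = c(0.5744, 0.7183, 0.4564))
#' m$h2
#' chain_model(h2 = 0.001)$r_squared
#' @export
chain_model <- function(maf = 0.25, beta = NULL, r_squared = NULL, h2 = NULL,
                        error_var = c(1, 1, 1), anchor = chain_anchor()) {
  check_maf(maf)
  check_error_var(error_var)
  given <- c(!is.null(beta), !is.null(r_squared), !is.null(h2))
  if (sum(given) != 1L) {
    stop_usage("Supply exactly one of `beta`, `r_squared` or `h2`.")
  }
  if (!is.null(h2)) {
    r_squared <- scale_to_heritability_(as_rsq(anchor), h2)
  }
  if (is.null(beta)) {
    beta <- params_from_correlations_(r_squared, maf, error_var)
  }
  beta <- unname(beta)
  rsq <- mediate_correlations_(maf, beta, error_var)
  structure(
    list(
      maf = maf,
      beta = beta,
      error_var = unname(error_var),
      variances = variance_chain_(maf, beta, error_var),
      r_squared = unname(rsq),
      h2 = prod(rsq),
      level_cor = trait_correlations_(unname(rsq))
    ),
    class = "chain_model"
  )
}

#' @export
print.chain_model <- function(x, ...) {
  cat("Causal chain model (genotype -> RNA -> protein -> trait)\n")
  cat(sprintf("  maf: %.4g   slopes: (%.4f, %.4f, %.4f)\n",
              x$maf, x$beta[1], x$beta[2], x$beta[3]))
  cat(sprintf("  error variances: (%g, %g, %g)\n",
              x$error_var[1], x$error_var[2], x$error_var[3]))
  cat(sprintf("  mediate r^2: (%.4f, %.4f, %.4f)   h^2: %.4f%%\n",
              x$r_squared[1], x$r_squared[2], x$r_squared[3], 100 * x$h2))
  cat(sprintf("  level-trait r^2: snp %.4f, rna %.4f, prt %.4f\n",
              x$level_cor[["snp"]], x$level_cor[["rna"]], x$level_cor[["prt"]]))
  invisible(x)
}

#' Tidy a chain model into a parameter table
#'
#' @param x A [chain_model()].
#' @param ... Unused.
#' @return A tibble with columns `term` and `value`, one row per structural
#'   parameter or derived correlation.
#' @export
tidy.chain_model <- function(x, ...) {
  tibble(
    term = c(
      "maf", "beta1", "beta2", "beta3",
      "var_e2", "var_e3", "var_e4",
      "r1sq", "r2sq", "r3sq", "h2",
      "cor2_snp_trait", "cor2_rna_trait", "cor2_prt_trait"
    ),
    value = c(
      x$maf, x$beta, x$error_var, x$r_squared, x$h2,
      unname(x$level_cor)
    )
  )
}

#' One-row summary of a chain model
#'
#' @inheritParams tidy.chain_model
#' @return A one-row tibble with the heritability, the mediate squared
#'   correlations and the squared level-trait correlations.
#' @export
glance.chain_model <- function(x, ...) {
  tibble(
    h2 = x$h2,
    r1sq = x$r_squared[1], r2sq = x$r_squared[2], r3sq = x$r_squared[3],
    cor2_snp = x$level_cor[["snp"]],
    cor2_rna = x$level_cor[["rna"]],
    cor2_prt = x$level_cor[["prt"]],
    var_y = x$variances[["var_y"]]
  )
}
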