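#' Truncated standard-normal tail moments
#'
#' For a per-tail truncation fraction `alpha`, the upper threshold is
#' \eqn{z = \Phi^{-1}(1-\alpha)}, the tail mean factor is
#' \eqn{\lambda = \phi(z)/\alpha} (the mean of a standard normal conditional
#' on exceeding \eqn{z}), the within-tail variance is
#' \eqn{1 + z\lambda - \lambda^2}, and the second moment conditional on
#' falling in either symmetric tail is \eqn{1 + z\lambda}. These moments
#' drive the behaviour of extreme phenotype sampling: \eqn{\lambda} sets the
#' between-tail separation of any predictor correlated with the trait, and
#' the within-tail variance sets its residual spread.
#'
#' @param alpha Per-tail truncation fraction(s) in (0, 0.5]. `alpha = 0.5`
#'   corresponds to a median split (no truncation gap).
#' @return A tibble with one row per `alpha` and columns `alpha`, `z`,
#'   `lambda`, `tail_var`, `sel_m2`.
#' @examples
#' tail_moments(c(0.5, 0.2, 0.1))
#' @export
tail_moments <- function(alpha) {
  check_alpha(alpha)
  z <- qnorm(1 - alpha)
  lambda <- dnorm(z) / alpha
  tibble(
    alpha = alpha,
    z = z,
    lambda = lambda,
    tail_var = 1 + z * lambda - lambda^2,
    sel_m2 = 1 + z * lambda
  )
}

tail_lambda <- function(alpha) {
  z <- qnorm(1 - alpha)
  dnorm(z) / alpha
}

tail_var_ <- function(alpha) {
  z <- qnorm(1 - alpha)
  lam <- dnorm(z) / alpha
  1 + z * lam - lam^2
}

#' Conditional moments of a correlated predictor under tail selection
#'
#' For a standardized predictor with population correlation `rho` to the
#' standardized trait, selection into the upper (lower) 100`alpha`% trait
#' tail shifts the predictor mean to \eqn{\pm\rho\lambda(\alpha)} and shrinks
#' its variance to \eqn{1 - \rho^2 (1 - \mathrm{tail\_var}(\alpha))}. This is
#' the selection theory behind the extreme-phenotype two-sample t-test.
#'
#' @param rho Population correlation(s) in (-1, 1).
#' @inheritParams tail_moments
#' @return A tibble with columns `rho`, `alpha`, `mean_upper`, `mean_lower`,
#'   `within_var`.
#' @examples
#' eps_predictor_moments(0.339, 0.2)
#' @export
eps_predictor_moments <- function(rho, alpha) {
  check_alpha(alpha)
  if (!is.numeric(rho) || anyNA(rho) || any(abs(rho) >= 1)) {
    stop_domain("`rho` must be correlations in (-1, 1).")
  }
  lam <- tail_lambda(alpha)
  tibble(
    rho = rho,
    alpha = alpha,
    mean_upper = rho * lam,
    mean_lower = -rho * lam,
    within_var = 1 - rho^2 * (1 - tail_var_(alpha))
  )
}

#' Convert a between-tail fold change to a squared protein-trait correlation
#'
#' Protein intensity is modelled as log-normal with standardized log
#' intensity; under tail selection at per-tail fraction `alpha`, the expected
#' between-tail difference in mean log intensity is
#' \eqn{2 r_3 \lambda(\alpha)}, so a reported fold change `fc` between the
#' upper and lower tails corresponds to
#' \eqn{r_3 = \ln(\mathrm{fc}) / (2\lambda(\alpha))}.
#'
#' @param fold_change Fold change(s) between upper- and lower-tail mean
#'   protein intensity, at least 1.
#' @param trunc_alpha Per-tail truncation fraction in (0, 0.5].
#' @return The squared protein-trait correlation(s) \eqn{r_3^2} in \[0, 1).
#' @examples
#' fold_change_to_r3sq(5, 0.2) # ~0.33
#' @seealso [r3sq_to_fold_change()] for the inverse.
#' @export
fold_change_to_r3sq <- function(fold_change, trunc_alpha = 0.2) {
  check_alpha(trunc_alpha)
  if (!is.numeric(fold_change) || anyNA(fold_change) || any(fold_change < 1)) {
    stop_domain("`fold_change` must be at least 1.")
  }
  r3 <- log(fold_change) / (2 * tail_lambda(trunc_alpha))
  if (any(r3 >= 1)) {
    stop_domain("`fold_change` implies a protein-trait correlation of 1 or more.")
  }
  r3^2
}

#' Convert a squared protein-trait correlation to a between-tail fold change
#'
#' Inverse of [fold_change_to_r3sq()]:
#' \eqn{\mathrm{fc} = \exp(2 \sqrt{r_3^2}\, \lambda(\alpha))}.
#'
#' @param r3sq Squared protein-trait correlation(s) in \[0, 1).
#' @inheritParams fold_change_to_r3sq
#' @return Fold change(s), at least 1.
#' @examples
#' r3sq_to_fold_change(0.3305, 0.2) # ~5
#' @export
r3sq_to_fold_change <- function(r3sq, trunc_alpha = 0.2) {
  check_alpha(trunc_alpha)
  if (!is.numeric(r3sq) || anyNA(r3sq) || any(r3sq < 0) || any(r3sq >= 1)) {
    stop_domain("`r3sq` must be squared correlations in [0, 1).")
  }
  exp(2 * sqrt(r3sq) * tail_lambda(trunc_alpha))
}
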