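# Empirical and theoretical signal-to-noise for the non-zero condition.

#' Empirical signal-to-noise of a replicate vector
#'
#' `mean(values) / sd(values)` with the sample (n-1) standard deviation.
#' A zero-variance vector yields `Inf` (maximally consistent signal) unless
#' its mean is also zero, in which case the S/N is 0.
#'
#' @param values numeric vector of length >= 2.
#' @return a single numeric S/N (possibly `Inf`).
#' @export
empirical_snr <- function(values) {
  if (!is.numeric(values) || length(values) < 2L) {
    stop("invalid-argument: need at least two replicate values", call. = FALSE)
  }
  m <- mean(values)
  s <- sd(values)
  if (s == 0) {
    if (m == 0) 0 else Inf
  } else {
    m / s
  }
}

#' Theoretical NB signal-to-noise
#'
#' For a negative-binomial gene with mean `mu` and variance
#' `mu * (1 + mu * phi)`, the population signal-to-noise is
#' `1 / sqrt(1 / mu + phi)`: it increases in `mu`, decreases in `phi`, and
#' saturates at `phi^(-1/2)` for large means (so at high expression the S/N
#' measures nothing but the inverse square root of the dispersion).
#'
#' @param mu positive NB mean (vectorized).
#' @param phi non-negative NB dispersion (vectorized).
#' @return numeric vector of theoretical S/N values.
#' @export
theoretical_snr <- function(mu, phi) {
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    stop("invalid-argument: mu must be positive and finite", call. = FALSE)
  }
  if (any(phi < 0)) {
    stop("invalid-argument: phi must be non-negative", call. = FALSE)
  }
  1 / sqrt(1 / mu + phi)
}

#' S/N table for all-zero-in-one-condition genes
#'
#' Restricts to genes whose raw counts are zero in every replicate of exactly
#' one condition and computes the empirical S/N on the normalized values of
#' the other condition.
#'
#' @param matrix a `norm_matrix` on the scale the S/N should be computed on.
#' @param design two-level factor.
#' @param raw_counts raw count matrix sharing gene IDs with `matrix`.
#' @return data.frame with columns `gene_id`, `scale`, `condition_used`,
#'   `n_used`, `snr`; empty (zero rows) when no gene qualifies.
#' @export
snr_table <- function(matrix, design, raw_counts) {
  mv <- mean_var_table(matrix, design, raw_counts)
  snr <- ifelse(mv$sd == 0, ifelse(mv$mean == 0, 0, Inf), mv$mean / mv$sd)
  data.frame(gene_id = mv$gene_id,
             scale = rep(matrix$scale, nrow(mv)),
             condition_used = mv$condition_used,
             n_used = mv$n_used,
             snr = snr,
             stringsAsFactors = FALSE)
}

#' Theoretical S/N across a parameter pool
#'
#' One row per pool entry, suitable for plotting the S/N--dispersion
#' relationship (S/N against `phi^(-1/2)`).
#'
#' @param pool a `param_pool`.
#' @return data.frame with columns `mu`, `phi`, `snr`.
#' @export
snr_dispersion_curve <- function(pool) {
  stopifnot(inherits(pool, "param_pool"), length(pool$mu) >= 1)
  data.frame(mu = pool$mu, phi = pool$phi,
             snr = theoretical_snr(pool$mu, pool$phi))
}
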