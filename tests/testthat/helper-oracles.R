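# Independent reference implementations used as oracles.  Each is written
# straight from the defining formula, separately from the package code paths
# it checks.

# Brute-force TMM: explicit sort-based trimming, no rank() shortcuts.
tmm_oracle <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  lib <- colSums(counts)
  cpm0 <- t(t(counts) / lib) * 1e6
  uq <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) uq[j] <- quantile(cpm0[, j], 0.75, names = FALSE)
  ref <- which.min(abs(uq - mean(uq)))

  one <- function(j) {
    x <- counts[, j]; r <- counts[, ref]
    idx <- which(x > 0 & r > 0)
    if (length(idx) == 0) return(1)
    M <- log2((x[idx] / lib[j]) / (r[idx] / lib[ref]))
    if (max(abs(M)) < 1e-10) return(1)
    A <- 0.5 * log2((x[idx] / lib[j]) * (r[idx] / lib[ref]))
    w <- 1 / ((lib[j] - x[idx]) / (lib[j] * x[idx]) +
                (lib[ref] - r[idx]) / (lib[ref] * r[idx]))
    n <- length(idx)
    # stable order by (value, original index), then cut both tails
    in_band <- function(v, trim) {
      ord <- order(v, seq_along(v))
      lo <- floor(n * trim) + 1
      hi <- n + 1 - lo
      keep <- logical(n)
      if (hi >= lo) keep[ord[lo:hi]] <- TRUE
      keep
    }
    keep <- in_band(M, trim_m) & in_band(A, trim_a)
    if (!any(keep)) return(1)
    2^(weighted.mean(M[keep], w[keep]))
  }
  f <- vapply(seq_len(ncol(counts)), one, numeric(1))
  f / exp(mean(log(f)))
}

# Exhaustive two-sided conditional NB P value: explicit log-pmf via lgamma,
# full enumeration of every split of the total s.
nb_doubletail_oracle <- function(sa, s, nA, nB, phi) {
  if (s == 0) return(1)
  mu <- s / (nA + nB)
  lpmf <- function(k, n) {
    m <- n * mu
    if (phi == 0) {
      k * log(m) - m - lgamma(k + 1)
    } else {
      r <- n / phi
      lgamma(k + r) - lgamma(r) - lgamma(k + 1) +
        r * log(r / (r + m)) + k * log(m / (r + m))
    }
  }
  k <- 0:s
  lp <- lpmf(k, nA) + lpmf(s - k, nB)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  pobs <- p[sa + 1]
  sum(p[p <= pobs * (1 + 1e-8)])
}

# Pairwise-concordance AUC: (concordant + 0.5 * tied) / (npos * nneg).
auc_pairwise_oracle <- function(scores, is_true) {
  pos <- scores[is_true]
  neg <- scores[!is_true]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# generalized-log closed form, restated independently
glog2_ref <- function(x, c) log2((x + sqrt(x^2 + c^2)) / 2)
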