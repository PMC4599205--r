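# Surrogate DE tests: conditional exact NB test on counts and a
# precision-weighted moderated t on log-CPM; dispersion estimation with a
# mean trend and shrinkage; BH adjustment; external-results adapter.

#' Moment dispersion estimates with a mean trend and shrinkage
#'
#' Per-gene NB dispersions on library-size-adjusted counts (counts rescaled
#' to the geometric-mean library): the moment estimate is
#' `max(0, (pooled within-group variance - mean) / mean^2)`, the trend is a
#' running median of the moment estimates over genes ordered by mean (window
#' 101, ends padded by extension), and the shrunk estimate is the convex
#' combination `shrink_weight * trend + (1 - shrink_weight) * moment`.
#'
#' With `basis = "single-nonzero-condition"` only genes that are all zero in
#' exactly one condition are returned, with moments computed from the
#' replicates of the other condition alone.
#'
#' @param counts integer gene x sample matrix.
#' @param design two-level factor.
#' @param basis `"both-conditions"` or `"single-nonzero-condition"`.
#' @param shrink_weight weight of the trend in the shrunk estimate, in
#'   `[0, 1]`.
#' @return data.frame with columns `gene_id`, `mean`, `phi_moment`,
#'   `phi_trend`, `phi_shrunk`, `basis`.
#' @export
estimate_dispersions <- function(counts, design,
                                 basis = c("both-conditions",
                                           "single-nonzero-condition"),
                                 shrink_weight = 0.7) {
  assert_count_matrix(counts, allow_real = TRUE)
  design <- assert_design(design, counts)
  basis <- match.arg(basis)
  stopifnot(shrink_weight >= 0, shrink_weight <= 1)
  lv <- levels(design)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("invalid-input: sample with zero total", call. = FALSE)
  geo <- exp(mean(log(lib)))
  y <- sweep(counts, 2, geo / lib, "*")

  if (basis == "both-conditions") {
    if (any(tabulate(design) < 2L)) {
      stop("invalid-design: every group needs >= 2 replicates", call. = FALSE)
    }
    iA <- design == lv[1]; iB <- design == lv[2]
    nA <- sum(iA); nB <- sum(iB)
    ssA <- rowSums((y[, iA, drop = FALSE] - rowMeans(y[, iA, drop = FALSE]))^2)
    ssB <- rowSums((y[, iB, drop = FALSE] - rowMeans(y[, iB, drop = FALSE]))^2)
    v <- (ssA + ssB) / (nA + nB - 2)
    m <- rowMeans(y)
    gene_id <- rownames(counts)
  } else {
    zc <- zero_condition(counts, design)
    sel <- which(zc %in% lv)
    if (length(sel) == 0) {
      return(data.frame(gene_id = character(0), mean = numeric(0),
                        phi_moment = numeric(0), phi_trend = numeric(0),
                        phi_shrunk = numeric(0), basis = character(0),
                        stringsAsFactors = FALSE))
    }
    other <- ifelse(zc[sel] == lv[1], lv[2], lv[1])
    if (any(tabulate(design) < 2L)) {
      stop("invalid-design: every group needs >= 2 replicates", call. = FALSE)
    }
    m <- v <- numeric(length(sel))
    for (k in seq_along(sel)) {
      vals <- y[sel[k], design == other[k]]
      m[k] <- mean(vals)
      v[k] <- var(vals)
    }
    gene_id <- rownames(counts)[sel]
  }

  phi_moment <- ifelse(m > 0, pmax(0, (v - m) / m^2), 0)
  phi_trend <- running_median_trend(phi_moment, m)
  phi_shrunk <- shrink_weight * phi_trend + (1 - shrink_weight) * phi_moment
  data.frame(gene_id = gene_id, mean = m,
             phi_moment = phi_moment, phi_trend = phi_trend,
             phi_shrunk = phi_shrunk, basis = basis,
             stringsAsFactors = FALSE)
}

# running median of x over genes ordered by m; window w (odd), ends padded
# by extending the terminal values
running_median_trend <- function(x, m, w = 101L) {
  n <- length(x)
  if (n == 0) return(numeric(0))
  if (n == 1) return(x)
  w <- min(w, if (n %% 2L == 1L) n else n - 1L)
  if (w < 3L) return(x)
  ord <- order(m, seq_len(n))
  xs <- x[ord]
  h <- (w - 1L) %/% 2L
  pad <- c(rep(xs[1], h), xs, rep(xs[n], h))
  tr <- vapply(seq_len(n), function(i) median(pad[i:(i + w - 1L)]), numeric(1))
  out <- numeric(n)
  out[ord] <- tr
  out
}

#' Benjamini--Hochberg FDR adjustment
#'
#' Step-up adjustment of a P-value vector (wraps [stats::p.adjust]).
#'
#' @param pvalues numeric vector with values in `[0, 1]`.
#' @return numeric vector of adjusted values (estimated FDRs).
#' @export
adjust_bh <- function(pvalues) {
  if (!is.numeric(pvalues) || any(!is.finite(pvalues)) ||
      any(pvalues < 0 | pvalues > 1)) {
    stop("invalid-input: P values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

# two-sided conditional exact NB P value for an observed group-A sum `sa`
# out of total `s`, with nA and nB samples per group and dispersion phi.
# Conditions on s: the group-A sum follows the convolution-ratio law
# p(k) ~ dNB(k; nA*mu, phi/nA) * dNB(s-k; nB*mu, phi/nB); the two-sided P
# sums the probabilities of all outcomes as or less likely than observed.
exact_nb_pvalue <- function(sa, s, nA, nB, phi) {
  if (s == 0) return(1)
  mu <- s / (nA + nB)
  poisson <- phi < 1e-12
  if (s <= 5000L) {
    k <- 0:s
  } else {
    if (poisson) {
      loA <- qbinom(1e-15, s, nA / (nA + nB))
      hiA <- qbinom(1e-15, s, nA / (nA + nB), lower.tail = FALSE)
      k <- max(0, min(loA, sa)):min(s, max(hiA, sa))
    } else {
      loA <- qnbinom(1e-15, size = nA / phi, mu = nA * mu)
      hiA <- qnbinom(1e-15, size = nA / phi, mu = nA * mu, lower.tail = FALSE)
      loB <- qnbinom(1e-15, size = nB / phi, mu = nB * mu)
      hiB <- qnbinom(1e-15, size = nB / phi, mu = nB * mu, lower.tail = FALSE)
      lo <- max(0, loA, s - hiB)
      hi <- min(s, hiA, s - loB)
      k <- max(0, min(lo, sa)):min(s, max(hi, sa))
    }
  }
  if (poisson) {
    lp <- dbinom(k, s, nA / (nA + nB), log = TRUE)
  } else {
    lp <- dnbinom(k, size = nA / phi, mu = nA * mu, log = TRUE) +
      dnbinom(s - k, size = nB / phi, mu = nB * mu, log = TRUE)
  }
  p <- exp(lp - max(lp))
  pobs <- p[k == sa]
  min(1, sum(p[p <= pobs * (1 + 1e-8)]) / sum(p))
}

#' Conditional exact negative-binomial test
#'
#' A transparent surrogate for the count-based DE family.  Effective library
#' sizes (library size times normalization factor) are first equalized by
#' scaling every sample's counts to the geometric-mean effective library and
#' rounding half-up.  Per gene, the test conditions on the total count
#' `s = sA + sB` and computes the two-sided exact P value as the summed
#' probability of all splits of `s` that are as or less likely than the
#' observed one under NB group sums with the gene's (shrunk) dispersion;
#' dispersion 0 reduces to the conditional binomial (Poisson) test.
#'
#' @param counts integer gene x sample matrix.
#' @param design two-level factor.
#' @param dispersions output of [estimate_dispersions()]; estimated from
#'   `counts` when `NULL`.
#' @param factors per-sample normalization factors; TMM when `NULL`.
#' @return data.frame with columns `gene_id`, `pvalue`, `fdr` (BH over all
#'   genes), `method = "exact-nb"`.
#' @export
exact_nb_test <- function(counts, design, dispersions = NULL, factors = NULL) {
  assert_count_matrix(counts, allow_real = TRUE)
  design <- assert_design(design, counts)
  if (is.null(factors)) factors <- tmm_factors(counts)
  if (is.null(dispersions)) dispersions <- estimate_dispersions(counts, design)
  lv <- levels(design)
  eff <- colSums(counts) * factors
  target <- exp(mean(log(eff)))
  eq <- floor(sweep(counts, 2, target / eff, "*") + 0.5)  # half-up rounding

  iA <- design == lv[1]; iB <- design == lv[2]
  nA <- sum(iA); nB <- sum(iB)
  sA <- rowSums(eq[, iA, drop = FALSE])
  sB <- rowSums(eq[, iB, drop = FALSE])
  phi <- dispersions$phi_shrunk[match(rownames(counts), dispersions$gene_id)]
  if (any(is.na(phi))) {
    stop("invalid-input: dispersions missing for some genes", call. = FALSE)
  }
  p <- vapply(seq_len(nrow(eq)), function(g) {
    exact_nb_pvalue(sA[g], sA[g] + sB[g], nA, nB, phi[g])
  }, numeric(1))
  data.frame(gene_id = rownames(counts), pvalue = p, fdr = adjust_bh(p),
             method = "exact-nb", stringsAsFactors = FALSE)
}

# trigamma inverse by Newton iteration (monotone decreasing target)
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

# moment-match a scaled-F model to per-gene variances s2 with d residual df:
# var(log s2) across genes = trigamma(d/2) + trigamma(d0/2); below that floor
# the prior df d0 is infinite.
fit_var_prior <- function(s2, d) {
  z <- log(pmax(s2, 1e-12))
  e <- z - digamma(d / 2) + log(d / 2)
  ev <- var(e) - trigamma(d / 2)
  if (is.finite(ev) && ev > 1e-8) {
    d0 <- 2 * trigamma_inverse(ev)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    # all variances identical: no sampling scatter to correct for
    s02 <- if (var(z) == 0) mean(s2) else exp(mean(e))
  }
  list(d0 = d0, s02 = s02)
}

#' Precision-weighted moderated t test on log-CPM
#'
#' A transparent surrogate for the transform-based DE family.  The pipeline:
#' (a) fit a lowess trend of per-gene square-root residual standard deviation
#' on average log-CPM; (b) convert the trend into per-observation precision
#' weights evaluated at each observation's fitted group mean; (c) refit the
#' two-group model per gene by weighted least squares; (d) moderate the
#' residual variances by empirical Bayes, with the prior degrees of freedom
#' and variance obtained by moment-matching the distribution of log variances
#' across genes; (e) refer the moderated t statistic to a t distribution with
#' augmented degrees of freedom (normal when the prior df is infinite).
#'
#' @param logdata a `norm_matrix` of scale `"log-cpm"`.
#' @param design two-level factor.
#' @param raw_counts raw counts (currently used for ID checks only; the
#'   abundance axis of the trend is the average log-CPM).
#' @return data.frame with columns `gene_id`, `pvalue`, `fdr`,
#'   `method = "moderated-t"`, plus `t` and `df_total`.
#' @export
moderated_t_test <- function(logdata, design, raw_counts = NULL) {
  stopifnot(inherits(logdata, "norm_matrix"), logdata$scale == "log-cpm")
  y <- logdata$values
  design <- assert_design(design, y)
  if (!is.null(raw_counts)) {
    stopifnot(identical(rownames(y), rownames(raw_counts)))
  }
  lv <- levels(design)
  iA <- design == lv[1]; iB <- design == lv[2]
  nA <- sum(iA); nB <- sum(iB)
  if (nA < 2L || nB < 2L) {
    stop("invalid-design: >= 2 samples per group required", call. = FALSE)
  }
  d <- nA + nB - 2L
  mA <- rowMeans(y[, iA, drop = FALSE])
  mB <- rowMeans(y[, iB, drop = FALSE])
  fitted <- matrix(NA_real_, nrow(y), ncol(y), dimnames = dimnames(y))
  fitted[, iA] <- mA
  fitted[, iB] <- mB
  s2 <- rowSums((y - fitted)^2) / d

  # mean-variance trend on sqrt-sd, evaluated at the fitted values
  avexp <- rowMeans(y)
  lo <- lowess(avexp, sqrt(sqrt(s2)), f = 0.5)
  pred <- approx(lo$x, lo$y, xout = as.vector(fitted), rule = 2,
                 ties = mean)$y
  pred <- pmax(pred, 1e-4)
  w <- matrix(1 / pred^4, nrow(y), ncol(y))

  WA <- rowSums(w[, iA, drop = FALSE])
  WB <- rowSums(w[, iB, drop = FALSE])
  mAw <- rowSums(w[, iA, drop = FALSE] * y[, iA, drop = FALSE]) / WA
  mBw <- rowSums(w[, iB, drop = FALSE] * y[, iB, drop = FALSE]) / WB
  beta <- mBw - mAw
  fw <- matrix(NA_real_, nrow(y), ncol(y))
  fw[, iA] <- mAw
  fw[, iB] <- mBw
  s2w <- rowSums(w * (y - fw)^2) / d

  prior <- fit_var_prior(s2w, d)
  s2_tilde <- if (is.finite(prior$d0)) {
    (prior$d0 * prior$s02 + d * s2w) / (prior$d0 + d)
  } else {
    rep(prior$s02, length(s2w))
  }
  se <- sqrt(s2_tilde * (1 / WA + 1 / WB))
  tstat <- ifelse(se > 0, beta / se, 0)
  df_total <- prior$d0 + d
  p <- 2 * pt(-abs(tstat), df = df_total)
  data.frame(gene_id = rownames(y), pvalue = p, fdr = adjust_bh(p),
             method = "moderated-t", t = tstat, df_total = df_total,
             stringsAsFactors = FALSE)
}

#' Load externally computed DE results
#'
#' Adapter that lets P values / FDRs produced by external tools (e.g. edgeR,
#' voom or DESeq runs) enter the evaluation.  Rows are validated against the
#' DE-result invariants; a missing FDR column is recomputed by [adjust_bh()].
#'
#' @param path TSV file with a header.
#' @param id_col,p_col,fdr_col column names holding the gene ID, P value and
#'   (optionally) FDR.
#' @param method tag recorded in the `method` column.
#' @return data.frame with columns `gene_id`, `pvalue`, `fdr`, `method`.
#' @export
load_external_results <- function(path, id_col = "gene_id", p_col = "pvalue",
                                  fdr_col = "fdr", method = "external") {
  if (!file.exists(path)) {
    stop(sprintf("I/O error: cannot read results file '%s'", path),
         call. = FALSE)
  }
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!(id_col %in% names(tab)) || !(p_col %in% names(tab))) {
    stop(sprintf("schema error: required columns '%s' and '%s' not found",
                 id_col, p_col), call. = FALSE)
  }
  p <- as.numeric(tab[[p_col]])
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("invalid-input: P values must lie in [0, 1]", call. = FALSE)
  }
  if (fdr_col %in% names(tab)) {
    fdr <- as.numeric(tab[[fdr_col]])
    if (any(!is.finite(fdr)) || any(fdr < 0 | fdr > 1)) {
      stop("invalid-input: FDR values must lie in [0, 1]", call. = FALSE)
    }
  } else {
    fdr <- adjust_bh(p)
  }
  data.frame(gene_id = as.character(tab[[id_col]]), pvalue = p, fdr = fdr,
             method = method, stringsAsFactors = FALSE)
}

#' Dispersion-shift diagnostic for zero-injected genes
#'
#' Checks whether estimating the dispersion from the single non-zero
#' condition of an all-zero-in-one-condition gene drastically shrinks it
#' relative to the both-conditions estimate.  For every truth-true gene the
#' table pairs (i) the moment dispersion from the non-zero condition of the
#' modified data with (ii) the both-conditions estimate on the unmodified
#' data when supplied (simulation), or otherwise the estimate of the
#' expression-matched nearest non-zero gene of the modified data.
#'
#' @param counts modified (zero-injected) count matrix.
#' @param design two-level factor.
#' @param truth truth data.frame with `gene_id` and `label` columns.
#' @param original_counts optional unmodified count matrix.
#' @return data.frame with columns `gene_id`, `phi_single`, `phi_both`,
#'   `reference` (`"original-data"` or `"expression-matched"`).
#' @export
dispersion_shift_diagnostic <- function(counts, design, truth,
                                        original_counts = NULL) {
  assert_count_matrix(counts, allow_real = TRUE)
  design <- assert_design(design, counts)
  true_genes <- truth$gene_id[truth$label == "true"]
  if (length(true_genes) == 0) {
    return(data.frame(gene_id = character(0), phi_single = numeric(0),
                      phi_both = numeric(0), reference = character(0),
                      stringsAsFactors = FALSE))
  }
  single <- estimate_dispersions(counts, design,
                                 basis = "single-nonzero-condition")
  single <- single[single$gene_id %in% true_genes, , drop = FALSE]

  if (!is.null(original_counts)) {
    both <- estimate_dispersions(original_counts, design,
                                 basis = "both-conditions")
    phi_both <- both$phi_moment[match(single$gene_id, both$gene_id)]
    reference <- "original-data"
  } else {
    both <- estimate_dispersions(counts, design, basis = "both-conditions")
    zc <- zero_condition(counts, design)
    nonzero <- both[zc[both$gene_id] == "none", , drop = FALSE]
    if (nrow(nonzero) == 0) {
      stop("invalid-input: no fully expressed genes available for matching",
           call. = FALSE)
    }
    phi_both <- vapply(single$mean, function(m) {
      nonzero$phi_moment[which.min(abs(nonzero$mean - m))]
    }, numeric(1))
    reference <- "expression-matched"
  }
  data.frame(gene_id = single$gene_id, phi_single = single$phi_moment,
             phi_both = phi_both, reference = reference,
             stringsAsFactors = FALSE)
}
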