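# TMM normalization, CPM, log-CPM and a generalized-log VST.

new_norm_matrix <- function(values, scale, factors, libsizes, params = list()) {
  structure(list(values = values, scale = scale, factors = factors,
                 libsizes = libsizes, params = params),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("norm_matrix [%s]: %d genes x %d samples\n", x$scale,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Trimmed mean of M-values normalization factors
#'
#' Computes per-sample scaling factors by the TMM recipe: the reference
#' sample is the one whose upper-quartile CPM is closest to the mean
#' upper-quartile; for every sample, log2 ratios (M) against the reference
#' are formed over genes with positive counts in both, doubly trimmed by M
#' (`trim_m` off each end) and by average abundance A (`trim_a` off each
#' end), and averaged with inverse asymptotic-variance weights; the factor is
#' 2 to that mean.  Factors are rescaled so their geometric mean is 1.
#' Trimming ranks break ties by gene order, so results are deterministic.
#'
#' @param counts numeric gene x sample matrix; every sample must have a
#'   positive total.
#' @param trim_m fraction trimmed from each tail of the M distribution.
#' @param trim_a fraction trimmed from each tail of the A distribution.
#' @return numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  assert_count_matrix(counts, allow_real = TRUE)
  if (ncol(counts) < 2L) {
    stop("invalid-input: TMM needs at least two samples", call. = FALSE)
  }
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    stop("invalid-input: sample with all-zero counts", call. = FALSE)
  }
  cpm0 <- sweep(counts, 2, lib, "/") * 1e6
  uq <- apply(cpm0, 2, quantile, probs = 0.75, names = FALSE)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

tmm_pair <- function(x, r, Lx, Lr, trim_m, trim_a) {
  keep <- x > 0 & r > 0
  if (!any(keep)) return(1)
  x <- x[keep]; r <- r[keep]
  px <- x / Lx; pr <- r / Lr
  M <- log2(px / pr)
  if (max(abs(M)) < 1e-10) return(1)
  A <- 0.5 * log2(px * pr)
  v <- (Lx - x) / (Lx * x) + (Lr - r) / (Lr * r)  # asymptotic var of M
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(1)
  2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
}

#' Counts-per-million
#'
#' `value(g, j) = (count(g, j) + prior) / (libsize_j * factor_j) * 1e6`,
#' with library sizes taken as column sums.  With `prior = 0`, every column
#' sums to `1e6 / factor_j` exactly.
#'
#' @param counts numeric gene x sample matrix.
#' @param factors per-sample normalization factors (default all 1).
#' @param prior non-negative pseudo-count added before scaling.
#' @return a `norm_matrix` with scale `"linear-cpm"`.
#' @export
cpm <- function(counts, factors = NULL, prior = 0) {
  assert_count_matrix(counts, allow_real = TRUE)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  stopifnot(length(factors) == ncol(counts), all(factors > 0),
            all(is.finite(factors)), prior >= 0)
  lib <- colSums(counts)
  values <- sweep(counts + prior, 2, lib * factors, "/") * 1e6
  new_norm_matrix(values, "linear-cpm", factors, lib, list(prior = prior))
}

#' Log2 counts-per-million
#'
#' `log2(cpm + offset)`; strictly monotone in the CPM value.
#'
#' @param cpm_matrix a `norm_matrix` of scale `"linear-cpm"`.
#' @param offset positive offset keeping the log defined at zero.
#' @return a `norm_matrix` with scale `"log-cpm"`.
#' @export
log_cpm <- function(cpm_matrix, offset = 0.5) {
  stopifnot(inherits(cpm_matrix, "norm_matrix"),
            cpm_matrix$scale == "linear-cpm", offset > 0)
  values <- log2(cpm_matrix$values + offset)
  new_norm_matrix(values, "log-cpm", cpm_matrix$factors, cpm_matrix$libsizes,
                  c(cpm_matrix$params, list(offset = offset)))
}

glog2 <- function(x, c) log2((x + sqrt(x^2 + c^2)) / 2)

#' Generalized-log variance-stabilizing transform
#'
#' Applies `glog2(x; c) = log2((x + sqrt(x^2 + c^2)) / 2)` to the CPM values,
#' with the crossover constant `c` calibrated to flatten the mean--sd trend:
#' per-gene variance is robustly regressed on squared mean
#' (`sd^2 ~ a + b * mean^2`, via [MASS::rlm]) and `c = sqrt(a / b)`.  When
#' the fit degenerates (non-positive `a` or `b`, or too few genes) the
#' transform falls back to `c = 1` with a logged warning.  For `x >> c` the
#' transform approaches `log2(x)`; at `x = 0` it equals `log2(c / 2)`.
#'
#' @param counts numeric gene x sample matrix.
#' @param factors per-sample normalization factors (default all 1).
#' @return a `norm_matrix` with scale `"vst"`; the calibrated `c` is stored
#'   in `$params$c`.
#' @export
vst <- function(counts, factors = NULL) {
  assert_count_matrix(counts, allow_real = TRUE)
  if (ncol(counts) < 2L) {
    stop("invalid-input: vst needs at least two samples", call. = FALSE)
  }
  cm <- cpm(counts, factors, prior = 0)
  m <- rowMeans(cm$values)
  s <- apply(cm$values, 1, sd)
  keep <- is.finite(m) & is.finite(s) & m > 0
  cc <- 1
  if (sum(keep) >= 10) {
    fit <- tryCatch(
      MASS::rlm(y ~ x, data = data.frame(x = m[keep]^2, y = s[keep]^2),
                maxit = 50),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (!is.null(fit)) {
      a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
      if (is.finite(a) && is.finite(b) && a > 0 && b > 0) {
        cc <- sqrt(a / b)
      } else {
        zio_log("warn", "vst: degenerate mean-sd fit (a=%.3g, b=%.3g); using c = 1", a, b)
      }
    } else {
      zio_log("warn", "vst: mean-sd fit failed; using c = 1")
    }
  } else {
    zio_log("warn", "vst: too few genes for calibration; using c = 1")
  }
  values <- glog2(cm$values, cc)
  new_norm_matrix(values, "vst", cm$factors, cm$libsizes, list(c = cc))
}

#' Per-gene mean and sd within the non-zero condition
#'
#' For genes whose raw counts are all zero in exactly one condition, computes
#' the mean and sample standard deviation of the normalized values over the
#' replicates of the other condition.  Genes all zero in both conditions, or
#' expressed in both, are excluded.
#'
#' @param matrix a `norm_matrix` on any scale.
#' @param design two-level factor.
#' @param raw_counts the raw count matrix used to determine the zero pattern.
#' @return data.frame with columns `gene_id`, `condition_used`, `n_used`,
#'   `mean`, `sd`.
#' @export
mean_var_table <- function(matrix, design, raw_counts) {
  stopifnot(inherits(matrix, "norm_matrix"))
  assert_count_matrix(raw_counts, allow_real = TRUE)
  design <- assert_design(design, raw_counts)
  stopifnot(identical(rownames(matrix$values), rownames(raw_counts)))
  zc <- zero_condition(raw_counts, design)
  lv <- levels(design)
  sel <- which(zc %in% lv)
  if (length(sel) == 0) {
    return(data.frame(gene_id = character(0), condition_used = character(0),
                      n_used = integer(0), mean = numeric(0), sd = numeric(0),
                      stringsAsFactors = FALSE))
  }
  cond_used <- ifelse(zc[sel] == lv[1], lv[2], lv[1])
  out <- data.frame(gene_id = rownames(raw_counts)[sel],
                    condition_used = cond_used,
                    n_used = NA_integer_, mean = NA_real_, sd = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(sel)) {
    cols <- which(design == cond_used[k])
    v <- matrix$values[sel[k], cols]
    out$n_used[k] <- length(v)
    out$mean[k] <- mean(v)
    out$sd[k] <- sd(v)
  }
  rownames(out) <- NULL
  out
}
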