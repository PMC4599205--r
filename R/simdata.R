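# Synthetic two-group NB count data with all-zero-in-one-condition DE genes.

# expected count `mu` in a parameter pool refers to this library size
REF_LIBSIZE <- 2e7

#' Simulation configuration
#'
#' Bundles all tunable parameters of the zero-in-one-condition simulation.
#' Defaults follow the benchmark design: 30,000 features in a 5 versus 5
#' two-group comparison, zeros injected into 5\% of features with a
#' preference for low expression, and library sizes typical of bulk RNA-seq
#' (16--39 million mapped reads).
#'
#' @param n_features number of simulated genes.
#' @param n_per_group integer pair, replicates in each group.
#' @param frac_zero_de fraction of features turned into all-zero-in-one-
#'   condition true DE genes.
#' @param phi_filter numeric pair, admissible dispersion range for the
#'   parameter pool.
#' @param low_expr_weight_exponent non-negative exponent of the rank-power
#'   weighting that concentrates zero injection at low expression; 0 gives
#'   uniform selection.
#' @param libsize_range integer pair, range of per-sample library sizes
#'   (drawn uniformly).
#' @param n_reps number of independent simulation replicates in a benchmark.
#' @param seed integer seed controlling all randomness.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_features = 30000L, n_per_group = c(5L, 5L),
                       frac_zero_de = 0.05, phi_filter = c(0, 5),
                       low_expr_weight_exponent = 1,
                       libsize_range = c(5e6, 4e7), n_reps = 3L,
                       seed = 1L) {
  stopifnot(n_features >= 1, length(n_per_group) == 2L, all(n_per_group >= 1),
            frac_zero_de >= 0, frac_zero_de <= 1,
            length(phi_filter) == 2L, phi_filter[1] <= phi_filter[2],
            low_expr_weight_exponent >= 0,
            length(libsize_range) == 2L, all(libsize_range > 0),
            libsize_range[1] <= libsize_range[2],
            n_reps >= 1)
  structure(list(n_features = as.integer(n_features),
                 n_per_group = as.integer(n_per_group),
                 frac_zero_de = frac_zero_de,
                 phi_filter = as.numeric(phi_filter),
                 low_expr_weight_exponent = low_expr_weight_exponent,
                 libsize_range = as.numeric(libsize_range),
                 n_reps = as.integer(n_reps),
                 seed = as.integer(seed)),
            class = "sim_config")
}

new_param_pool <- function(mu, phi, source) {
  stopifnot(length(mu) == length(phi))
  structure(list(mu = as.numeric(mu), phi = as.numeric(phi), source = source),
            class = "param_pool")
}

#' @export
print.param_pool <- function(x, ...) {
  cat(sprintf("param_pool (%s): %d entries, mu in [%.3g, %.3g], phi in [%.3g, %.3g]\n",
              x$source, length(x$mu), min(x$mu), max(x$mu),
              min(x$phi), max(x$phi)))
  invisible(x)
}

#' Parametric surrogate mean--dispersion pool
#'
#' Draws a joint pool of negative-binomial (mean, dispersion) pairs emulating
#' the structure of estimates from a large real RNA-seq dataset: log10 means
#' are normal with mean 1.5 and sd 1 (spanning roughly four orders of
#' magnitude of expression at a 20-million-read reference library), and
#' dispersions follow the decreasing trend `phi(mu) = 1/mu + 0.04` with
#' lognormal scatter (sdlog 0.5), clamped to `phi_filter`.  The `1/mu` term
#' reproduces the elevated dispersion of weakly expressed genes; the 0.04
#' asymptote corresponds to a biological coefficient of variation of 0.2.
#'
#' @param n number of entries.
#' @param seed integer seed; the pool is deterministic given the seed.
#' @param phi_filter admissible dispersion interval.
#' @return a `param_pool` with `source = "parametric-surrogate"`.
#' @export
make_surrogate_pool <- function(n, seed = 1L, phi_filter = c(0, 5)) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("invalid-argument: n must be >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  set.seed(derive_seed(seed, "surrogate-pool"))
  mu <- 10^rnorm(n, mean = 1.5, sd = 1)
  phi <- (1 / mu + 0.04) * exp(rnorm(n, 0, 0.5))
  phi <- pmin(pmax(phi, phi_filter[1]), phi_filter[2])
  new_param_pool(mu, phi, "parametric-surrogate")
}

#' Load a mean--dispersion pool from a two-column table
#'
#' Reads a TSV of per-gene NB mean and dispersion estimates (header optional),
#' drops rows with non-finite or non-positive means, negative dispersions, or
#' dispersions outside `phi_filter` (extreme-dispersion filtering), and
#' reports how many rows were removed.
#'
#' @param path path to a two-column numeric TSV (mean, dispersion).
#' @param phi_filter admissible dispersion interval.
#' @return a `param_pool` with `source = "empirical-file"`.
#' @export
load_param_pool <- function(path, phi_filter = c(0, 5)) {
  if (!file.exists(path)) {
    stop(sprintf("I/O error: cannot read parameter pool '%s'", path),
         call. = FALSE)
  }
  first <- strsplit(readLines(path, n = 1L), "\t|,| +")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  tab <- read.table(path, header = has_header, sep = "", comment.char = "#")
  if (ncol(tab) < 2L) {
    stop("schema error: parameter pool needs two columns (mean, dispersion)",
         call. = FALSE)
  }
  mu <- as.numeric(tab[[1]])
  phi <- as.numeric(tab[[2]])
  ok <- is.finite(mu) & is.finite(phi) & mu > 0 & phi >= 0 &
    phi >= phi_filter[1] & phi <= phi_filter[2]
  n_removed <- sum(!ok)
  if (n_removed > 0) {
    zio_log("info", "load_param_pool: removed %d of %d rows (invalid or outside phi filter [%g, %g])",
            n_removed, length(ok), phi_filter[1], phi_filter[2])
  }
  if (!any(ok)) {
    stop("empty-pool error: no rows survive validation/filtering", call. = FALSE)
  }
  new_param_pool(mu[ok], phi[ok], "empirical-file")
}

#' Simulate a null two-group NB count dataset
#'
#' Draws per-feature (mean, dispersion) pairs from the pool with replacement,
#' per-sample library sizes uniformly from `config$libsize_range`, and counts
#' from NB(mean = mu * L / Lref, dispersion = phi), identically in both groups
#' (no differential expression).  Dispersion 0 uses the Poisson limit.
#'
#' @param pool a `param_pool`.
#' @param config a [sim_config()].
#' @return a list of class `"sim_dataset"` with elements `counts` (integer
#'   matrix, genes x samples), `design` (two-level factor), `truth`
#'   (data.frame gene_id/label/zeroed_condition, all labels `"false"`),
#'   `params` (data.frame of the NB parameters used) and `target_libsizes`.
#' @export
simulate_null_counts <- function(pool, config = sim_config()) {
  stopifnot(inherits(pool, "param_pool"), length(pool$mu) >= 1)
  set.seed(derive_seed(config$seed, "simulate-null"))
  nf <- config$n_features
  npg <- config$n_per_group
  ns <- sum(npg)
  gene_id <- sprintf("g%05d", seq_len(nf))
  sample_id <- c(sprintf("A%d", seq_len(npg[1])), sprintf("B%d", seq_len(npg[2])))
  design <- factor(rep(c("A", "B"), npg))

  L <- floor(runif(ns, config$libsize_range[1], config$libsize_range[2] + 1))
  idx <- sample.int(length(pool$mu), nf, replace = TRUE)
  mu <- pool$mu[idx]
  phi <- pool$phi[idx]

  mean_mat <- outer(mu, L / REF_LIBSIZE)
  counts <- matrix(0L, nf, ns, dimnames = list(gene_id, sample_id))
  nbrow <- phi > 0
  if (any(nbrow)) {
    m <- mean_mat[nbrow, , drop = FALSE]
    counts[nbrow, ] <- rnbinom(length(m), mu = as.vector(m),
                               size = rep(1 / phi[nbrow], times = ns))
  }
  if (any(!nbrow)) {
    m <- mean_mat[!nbrow, , drop = FALSE]
    counts[!nbrow, ] <- rpois(length(m), lambda = as.vector(m))
  }
  storage.mode(counts) <- "integer"

  truth <- data.frame(gene_id = gene_id,
                      label = rep("false", nf),
                      zeroed_condition = rep(NA_character_, nf),
                      stringsAsFactors = FALSE)
  attr(truth, "scheme") <- "simulation"
  structure(list(counts = counts, design = design, truth = truth,
                 params = data.frame(gene_id = gene_id, mu = mu, phi = phi,
                                     stringsAsFactors = FALSE),
                 target_libsizes = setNames(L, sample_id),
                 config = config),
            class = "sim_dataset")
}

#' Inject all-zero conditions as ground-truth DE genes
#'
#' Selects exactly `round(frac_zero_de * n_features)` features without
#' replacement, with probability proportional to
#' `rank(mean expression, lowest first)^(-low_expr_weight_exponent)`
#' (exponent 0 = uniform), zeroes all counts of one condition chosen by a
#' fair coin per feature, and labels the feature `"true"`.  A draw whose
#' complementary condition is already all zero is rejected and replaced, so
#' every true feature has at least one positive count in the surviving
#' condition.  No other cell of the count matrix is touched.
#'
#' @param data a `sim_dataset` with all-false truth.
#' @param config the [sim_config()] in use (falls back to `data$config`).
#' @return the modified `sim_dataset`.
#' @export
introduce_zeros <- function(data, config = data$config) {
  stopifnot(inherits(data, "sim_dataset"))
  if (any(data$truth$label != "false")) {
    stop("invalid-input: introduce_zeros expects an all-null dataset",
         call. = FALSE)
  }
  nf <- nrow(data$counts)
  n_zero <- round(config$frac_zero_de * nf)
  if (n_zero == 0) return(data)

  set.seed(derive_seed(config$seed, "introduce-zeros"))
  lv <- levels(data$design)
  colsA <- which(data$design == lv[1])
  colsB <- which(data$design == lv[2])
  posA <- rowSums(data$counts[, colsA, drop = FALSE]) > 0
  posB <- rowSums(data$counts[, colsB, drop = FALSE]) > 0

  r <- rank(rowMeans(data$counts), ties.method = "first")
  w <- if (config$low_expr_weight_exponent > 0) {
    r^(-config$low_expr_weight_exponent)
  } else {
    rep(1, nf)
  }

  available <- rep(TRUE, nf)
  sel <- integer(0)
  sel_cond <- character(0)
  while (length(sel) < n_zero) {
    pool_idx <- which(available)
    need <- n_zero - length(sel)
    if (length(pool_idx) == 0) {
      stop("infeasible-selection error: not enough features with a non-zero condition",
           call. = FALSE)
    }
    take <- if (length(pool_idx) <= need) pool_idx else {
      sample(pool_idx, need, prob = w[pool_idx])
    }
    coin <- sample(lv, length(take), replace = TRUE)
    # feasible iff the condition NOT being zeroed has a positive count
    feas <- ifelse(coin == lv[1], posB[take], posA[take])
    available[take] <- FALSE
    sel <- c(sel, take[feas])
    sel_cond <- c(sel_cond, coin[feas])
  }

  counts <- data$counts
  for (k in seq_along(sel)) {
    cols <- if (sel_cond[k] == lv[1]) colsA else colsB
    counts[sel[k], cols] <- 0L
  }
  truth <- data$truth
  truth$label[sel] <- "true"
  truth$zeroed_condition[sel] <- sel_cond
  attr(truth, "scheme") <- "simulation"
  data$counts <- counts
  data$truth <- truth
  data
}

#' Zero-pattern frequency across the expression range
#'
#' Bins genes into `n_bins` equal-occupancy bins of average log2-CPM
#' (all-zero-in-one-condition genes use the mean of their non-zero condition,
#' other genes their overall mean) and reports, per bin, the share of all
#' all-zero-in-one-condition genes that fall in it.  With zeros concentrated
#' at low expression the shares decrease across bins.
#'
#' @param counts integer gene x sample matrix with rownames.
#' @param design two-level factor.
#' @param n_bins number of expression bins.
#' @return data.frame with columns `bin`, `mean_logcpm`, `n_genes`,
#'   `n_zero_genes`, `fraction`; `fraction` sums to 1 when any qualifying
#'   gene exists and is all zero otherwise.
#' @export
empirical_zero_profile <- function(counts, design, n_bins = 10L) {
  assert_count_matrix(counts, allow_real = TRUE)
  design <- assert_design(design, counts)
  zc <- zero_condition(counts, design)
  lv <- levels(design)
  lib <- colSums(counts)
  lib[lib == 0] <- 1
  logcpm <- log2(sweep(counts, 2, lib, "/") * 1e6 + 0.5)

  expr <- rowMeans(logcpm)
  for (g in which(zc %in% lv)) {
    other <- which(design != zc[g])
    expr[g] <- mean(logcpm[g, other])
  }
  n <- nrow(counts)
  n_bins <- min(n_bins, n)
  bin <- ceiling(rank(expr, ties.method = "first") * n_bins / n)
  is_zero_gene <- zc %in% lv
  total_zero <- sum(is_zero_gene)
  out <- data.frame(
    bin = seq_len(n_bins),
    mean_logcpm = as.numeric(tapply(expr, factor(bin, levels = seq_len(n_bins)),
                                    mean)),
    n_genes = as.integer(table(factor(bin, levels = seq_len(n_bins)))),
    n_zero_genes = as.integer(tapply(is_zero_gene,
                                     factor(bin, levels = seq_len(n_bins)),
                                     sum))
  )
  out$n_zero_genes[is.na(out$n_zero_genes)] <- 0L
  out$fraction <- if (total_zero > 0) out$n_zero_genes / total_zero else 0
  out
}

#' Extract simulation truth labels
#'
#' @param data a `sim_dataset`.
#' @return the truth data.frame (scheme `"simulation"`).
#' @export
truth_labels <- function(data) {
  stopifnot(inherits(data, "sim_dataset"))
  data$truth
}
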