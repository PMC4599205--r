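# Truth labels, ROC curves, TPR-vs-achieved-FDR and the benchmark driver.

#' Percentile truth labels from an S/N table
#'
#' Ranks genes by S/N descending (infinite S/N first; ties broken by gene ID
#' for determinism), labels the top `ceiling(true_top_fraction * n)` genes
#' `"true"`, the bottom `floor(false_bottom_fraction * n)` genes `"false"`,
#' and the remainder `"gray"`.  The same labels are meant to be reused for
#' every method being compared.
#'
#' @param snr_tbl data.frame with `gene_id` and `snr` columns (from
#'   [snr_table()]).
#' @param true_top_fraction fraction labeled true from the top.
#' @param false_bottom_fraction fraction labeled false from the bottom.
#' @return data.frame with columns `gene_id`, `label`; attribute `scheme`
#'   set to `"snr-percentile"`.
#' @export
percentile_labels <- function(snr_tbl, true_top_fraction = 0.40,
                              false_bottom_fraction = 0.20) {
  stopifnot(is.data.frame(snr_tbl), all(c("gene_id", "snr") %in% names(snr_tbl)))
  if (true_top_fraction <= 0 || false_bottom_fraction <= 0 ||
      true_top_fraction + false_bottom_fraction > 1) {
    stop("invalid-argument: fractions must be positive and sum to at most 1",
         call. = FALSE)
  }
  n <- nrow(snr_tbl)
  ord <- order(-snr_tbl$snr, snr_tbl$gene_id)
  n_true <- ceiling(true_top_fraction * n)
  n_false <- floor(false_bottom_fraction * n)
  label <- rep("gray", n)
  label[ord[seq_len(n_true)]] <- "true"
  if (n_false > 0) label[ord[seq.int(n - n_false + 1L, n)]] <- "false"
  out <- data.frame(gene_id = snr_tbl$gene_id, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "scheme") <- "snr-percentile"
  out
}

#' ROC curve over a gene ranking
#'
#' Standard ROC over descending score thresholds (tied scores grouped into
#' one operating point), with trapezoidal AUC.  Gray-labeled genes are
#' excluded before computation.  Optionally marks the operating point reached
#' at an estimated-FDR cutoff.
#'
#' @param scores named numeric vector of ranking scores (larger = more
#'   significant, e.g. `-log10` P).
#' @param labels truth data.frame with `gene_id` and `label`.
#' @param fdr optional named numeric vector of estimated FDRs aligned with
#'   `scores`, used to place `marker`.
#' @param fdr_cutoff cutoff for the marker (default 0.05).
#' @return list of class `"roc_curve"`: `points` (data.frame `fpr`, `tpr`),
#'   `auc`, and `marker` (`NULL` or a one-row data.frame).
#' @export
roc_curve <- function(scores, labels, fdr = NULL, fdr_cutoff = 0.05) {
  stopifnot(is.numeric(scores), !is.null(names(scores)),
            is.data.frame(labels))
  lab <- labels$label[match(names(scores), labels$gene_id)]
  keep <- !is.na(lab) & lab %in% c("true", "false")
  sc <- scores[keep]
  truth <- lab[keep] == "true"
  npos <- sum(truth)
  nneg <- sum(!truth)
  if (npos == 0 || nneg == 0) {
    stop("degenerate-labels error: need at least one true and one false gene",
         call. = FALSE)
  }
  ord <- order(-sc, names(sc))
  sc <- sc[ord]; truth <- truth[ord]
  # group tied scores: one operating point per distinct score
  last_of_tie <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- cumsum(truth)[last_of_tie]
  fp <- cumsum(!truth)[last_of_tie]
  points <- data.frame(fpr = c(0, fp / nneg), tpr = c(0, tp / npos))
  auc <- sum(diff(points$fpr) * (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)
  marker <- NULL
  if (!is.null(fdr)) {
    fd <- fdr[names(scores)][keep][ord]
    called <- !is.na(fd) & fd <= fdr_cutoff
    marker <- data.frame(fpr = sum(!truth & called) / nneg,
                         tpr = sum(truth & called) / npos,
                         cutoff = fdr_cutoff)
  }
  structure(list(points = points, auc = auc, marker = marker),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d points, auc = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' TPR versus achieved FDR
#'
#' At each nominal FDR cutoff, calls the genes with estimated FDR at or below
#' the cutoff and reports the achieved FDR (actual fraction of false
#' discoveries, 0 when nothing is called), the true positive rate, and
#' whether the error rate was controlled (achieved <= nominal).  Requires
#' hard simulation truth (no gray zone).
#'
#' @param results DE result data.frame (`gene_id`, `pvalue`, `fdr`).
#' @param truth truth data.frame with scheme `"simulation"`.
#' @param cutoffs nominal FDR cutoffs.
#' @return list with `performance` (one row per cutoff: `cutoff`, `n_called`,
#'   `achieved_fdr`, `tpr`, `controlled`) and `curve` (the full trace over
#'   all distinct estimated-FDR values).
#' @export
tpr_fdr_curve <- function(results, truth, cutoffs = c(0.01, 0.05, 0.1)) {
  stopifnot(is.data.frame(results), is.data.frame(truth))
  scheme <- attr(truth, "scheme")
  if (is.null(scheme) || scheme != "simulation") {
    stop("invalid-scheme error: achieved FDR needs simulation truth",
         call. = FALSE)
  }
  lab <- truth$label[match(results$gene_id, truth$gene_id)]
  keep <- !is.na(lab)
  res <- results[keep, , drop = FALSE]
  is_true <- lab[keep] == "true"
  npos <- sum(is_true)

  eval_at <- function(q) {
    called <- res$fdr <= q
    tp <- sum(called & is_true)
    fp <- sum(called & !is_true)
    data.frame(cutoff = q, n_called = tp + fp,
               achieved_fdr = fp / max(1, fp + tp),
               tpr = if (npos > 0) tp / npos else 0,
               controlled = (fp / max(1, fp + tp)) <= q)
  }
  performance <- do.call(rbind, lapply(cutoffs, eval_at))
  curve <- do.call(rbind, lapply(sort(unique(res$fdr)), eval_at))
  list(performance = performance, curve = curve)
}

#' Run the full simulation benchmark
#'
#' For each of `config$n_reps` independent simulations: generate a null NB
#' dataset, inject all-zero-condition true DE genes, TMM-normalize, run both
#' surrogate tests, and evaluate ROC (with the 5\% estimated-FDR marker) and
#' TPR-versus-achieved-FDR against the simulation truth.  Gene-level
#' (score, truth, fdr) records are pooled across replicates before one
#' overall curve per method is built; per-replicate curves are kept as well.
#' On the first replicate the percentile-label ROC is additionally computed
#' on the linear-CPM, log-CPM and VST scales, with labels recomputed on each
#' scale by default (`fix_label_scale = "linear-cpm"` reuses the linear
#' labels everywhere).
#'
#' @param config a [sim_config()].
#' @param pool optional `param_pool`; a surrogate pool of 20,000 entries is
#'   drawn from the config seed when `NULL`.
#' @param fix_label_scale `NULL` (recompute labels per scale) or the scale
#'   whose labels are reused for every panel.
#' @return a list of class `"benchmark_report"`.
#' @export
benchmark_run <- function(config = sim_config(), pool = NULL,
                          fix_label_scale = NULL) {
  if (is.null(pool)) {
    pool <- make_surrogate_pool(20000L, seed = derive_seed(config$seed, "pool"),
                                phi_filter = config$phi_filter)
  }
  methods <- c("exact-nb", "moderated-t")
  per_rep <- list()
  pooled <- setNames(vector("list", length(methods)), methods)
  for (m in methods) {
    pooled[[m]] <- data.frame(gene_id = character(0), score = numeric(0),
                              fdr = numeric(0), label = character(0),
                              stringsAsFactors = FALSE)
  }
  scale_roc <- NULL
  label_sets <- NULL

  for (r in seq_len(config$n_reps)) {
    cfg_r <- config
    cfg_r$seed <- derive_seed(config$seed, paste0("rep", r))
    sim <- introduce_zeros(simulate_null_counts(pool, cfg_r), cfg_r)
    zio_log("info", "benchmark rep %d: %d genes, %d true", r,
            nrow(sim$counts), sum(sim$truth$label == "true"))
    f <- tmm_factors(sim$counts)
    lin <- cpm(sim$counts, f)
    lg <- log_cpm(lin)
    disp <- estimate_dispersions(sim$counts, sim$design)
    res <- list(
      "exact-nb" = exact_nb_test(sim$counts, sim$design, disp, f),
      "moderated-t" = moderated_t_test(lg, sim$design, sim$counts)
    )
    truth <- sim$truth
    rep_out <- list(seed = cfg_r$seed, methods = list())
    for (m in methods) {
      rr <- res[[m]]
      score <- setNames(-log10(pmax(rr$pvalue, 1e-300)), rr$gene_id)
      fdr <- setNames(rr$fdr, rr$gene_id)
      roc <- roc_curve(score, truth, fdr = fdr, fdr_cutoff = 0.05)
      perf <- tpr_fdr_curve(rr, truth)
      rep_out$methods[[m]] <- list(roc = roc, fdr_performance = perf$performance)
      pooled[[m]] <- rbind(pooled[[m]], data.frame(
        gene_id = paste0("rep", r, ":", rr$gene_id),
        score = unname(score), fdr = rr$fdr,
        label = truth$label[match(rr$gene_id, truth$gene_id)],
        stringsAsFactors = FALSE))
    }
    per_rep[[r]] <- rep_out

    if (r == 1L) {
      vs <- vst(sim$counts, f)
      scales <- list("linear-cpm" = lin, "log-cpm" = lg, "vst" = vs)
      snr_tabs <- lapply(scales, snr_table, design = sim$design,
                         raw_counts = sim$counts)
      label_sets <- if (is.null(fix_label_scale)) {
        lapply(snr_tabs, percentile_labels)
      } else {
        fixed <- percentile_labels(snr_tabs[[fix_label_scale]])
        lapply(snr_tabs, function(...) fixed)
      }
      scale_roc <- lapply(names(scales), function(sc) {
        labs <- label_sets[[sc]]
        out <- lapply(methods, function(m) {
          rr <- res[[m]]
          score <- setNames(-log10(pmax(rr$pvalue, 1e-300)), rr$gene_id)
          tryCatch(roc_curve(score, labs), error = function(e) NULL)
        })
        setNames(out, methods)
      })
      names(scale_roc) <- names(scales)
    }
  }

  pooled_eval <- lapply(methods, function(m) {
    df <- pooled[[m]]
    labs <- data.frame(gene_id = df$gene_id, label = df$label,
                       stringsAsFactors = FALSE)
    attr(labs, "scheme") <- "simulation"
    score <- setNames(df$score, df$gene_id)
    fdr <- setNames(df$fdr, df$gene_id)
    rr <- data.frame(gene_id = df$gene_id, pvalue = 10^(-df$score),
                     fdr = df$fdr, stringsAsFactors = FALSE)
    list(roc = roc_curve(score, labs, fdr = fdr, fdr_cutoff = 0.05),
         fdr_performance = tpr_fdr_curve(rr, labs)$performance)
  })
  names(pooled_eval) <- methods

  structure(list(config = unclass(config), seed = config$seed,
                 per_rep = per_rep, pooled = pooled_eval,
                 scale_roc = scale_roc, label_sets = label_sets),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("benchmark_report: %d replicate(s), seed %d\n",
              length(x$per_rep), x$seed))
  for (m in names(x$pooled)) {
    cat(sprintf("  %-12s pooled AUC %.4f\n", m, x$pooled[[m]]$roc$auc))
  }
  invisible(x)
}
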