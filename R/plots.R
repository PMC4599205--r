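# ggplot2 figures: ROC by method/scale, TPR vs achieved FDR, mean-sd trends,
# zero-frequency profile.

#' Plot ROC curves
#'
#' One line per method; optional crosses mark each method's operating point
#' at the 5\% estimated-FDR cutoff.
#'
#' @param curves named list of `roc_curve` objects.
#' @return a ggplot object.
#' @export
plot_roc <- function(curves) {
  stopifnot(length(curves) >= 1, !is.null(names(curves)))
  pts <- do.call(rbind, lapply(names(curves), function(m) {
    cbind(curves[[m]]$points, method = m)
  }))
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                         colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_bw()
  marks <- do.call(rbind, lapply(names(curves), function(m) {
    mk <- curves[[m]]$marker
    if (is.null(mk)) NULL else cbind(mk, method = m)
  }))
  if (!is.null(marks) && nrow(marks) > 0) {
    p <- p + ggplot2::geom_point(data = marks, shape = 4, size = 3,
                                 stroke = 1.2)
  }
  p
}

#' Plot TPR versus achieved FDR
#'
#' Points at the nominal cutoffs are filled when the method controlled the
#' error rate (achieved FDR at or below nominal) and open otherwise.
#'
#' @param performance named list of FDR-performance data.frames (from
#'   [tpr_fdr_curve()] or a `benchmark_report`).
#' @return a ggplot object.
#' @export
plot_tpr_fdr <- function(performance) {
  stopifnot(length(performance) >= 1, !is.null(names(performance)))
  df <- do.call(rbind, lapply(names(performance), function(m) {
    cbind(performance[[m]], method = m)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$achieved_fdr, y = .data$tpr,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(fill = .data$method,
                                     alpha = .data$controlled),
                        shape = 21, size = 3) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0),
                                guide = "none") +
    ggplot2::labs(x = "Achieved FDR", y = "True positive rate") +
    ggplot2::theme_bw()
}

#' Plot mean--sd relationships across scales
#'
#' @param tables named list (by scale) of [mean_var_table()] outputs.
#' @return a ggplot object, faceted by scale.
#' @export
plot_mean_var <- function(tables) {
  stopifnot(length(tables) >= 1, !is.null(names(tables)))
  df <- do.call(rbind, lapply(names(tables), function(sc) {
    cbind(tables[[sc]], scale = sc)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = rank(.data$mean), y = .data$sd)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         colour = "red") +
    ggplot2::facet_wrap(~scale, scales = "free_y") +
    ggplot2::labs(x = "rank(mean)", y = "sd") +
    ggplot2::theme_bw()
}

#' Plot the zero-frequency profile across expression bins
#'
#' @param profile output of [empirical_zero_profile()].
#' @return a ggplot object.
#' @export
plot_zero_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$mean_logcpm,
                                        y = .data$fraction)) +
    ggplot2::geom_col(width = 0.8 * min(diff(sort(profile$mean_logcpm)),
                                        na.rm = TRUE)) +
    ggplot2::labs(x = "average log2-CPM (bin mean)",
                  y = "share of all-zero-in-one-condition genes") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 .data
NULL
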