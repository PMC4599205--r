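# TSV readers/writers and run configuration.

#' Read a count matrix from TSV/CSV
#'
#' First column = gene ID, header row = sample IDs, integer cells.
#' Duplicate gene IDs, negative or non-integer counts are rejected.
#'
#' @param path file path; tab- or comma-separated.
#' @return integer matrix with gene IDs as rownames.
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("I/O error: cannot read count matrix '%s'", path),
         call. = FALSE)
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("schema error: duplicated gene IDs", call. = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat) || any(!is.finite(mat))) {
    stop("schema error: counts must be numeric and finite", call. = FALSE)
  }
  if (any(mat < 0) || any(mat != floor(mat))) {
    stop("schema error: counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(mat) <- "integer"
  rownames(mat) <- ids
  mat
}

#' Write a count matrix as TSV
#'
#' @param counts matrix with gene IDs as rownames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column design table (sample ID, group)
#'
#' @param path TSV path.
#' @return named two-level factor (names = sample IDs).
#' @export
read_design <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("I/O error: cannot read design '%s'", path), call. = FALSE)
  }
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  d <- assert_design(factor(tab[[2]]))
  names(d) <- as.character(tab[[1]])
  d
}

#' Write a design table
#' @param design two-level factor with sample names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  write.table(data.frame(sample_id = names(design), group = as.character(design)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write truth labels (gene ID, label, zeroed condition)
#' @param truth truth data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read truth labels written by [write_truth()]
#' @param path TSV path.
#' @param scheme scheme tag to attach (`"simulation"` or `"snr-percentile"`).
#' @return truth data.frame.
#' @export
read_truth <- function(path, scheme = "simulation") {
  tab <- read.table(path, header = TRUE, sep = "\t", na.strings = "",
                    stringsAsFactors = FALSE)
  tab$gene_id <- as.character(tab$gene_id)
  attr(tab, "scheme") <- scheme
  tab
}

#' Write a parameter pool as two-column TSV (mean, dispersion)
#' @param pool a `param_pool`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_param_pool <- function(pool, path) {
  write.table(data.frame(mean = pool$mu, dispersion = pool$phi), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write DE results or S/N tables as TSV
#'
#' Serializes any of the pipeline's tabular outputs; infinite S/N values are
#' written as `"Inf"`.
#'
#' @param tab data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Write a normalized matrix with a sidecar JSON
#'
#' The values go to `<path>` as TSV; scale, factors, library sizes and
#' transform parameters go to `<path>.json`.
#'
#' @param nm a `norm_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_norm_matrix <- function(nm, path) {
  df <- data.frame(gene_id = rownames(nm$values), nm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(scale = nm$scale, factors = as.list(nm$factors),
               libsizes = as.list(nm$libsizes), params = nm$params)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a normalized matrix written by [write_norm_matrix()]
#' @param path TSV path (the sidecar `<path>.json` must exist).
#' @return a `norm_matrix`.
#' @export
read_norm_matrix <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- as.character(tab[[1]])
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_norm_matrix(values, meta$scale, unlist(meta$factors),
                  unlist(meta$libsizes), as.list(meta$params))
}

#' Resolve a run configuration
#'
#' Merges defaults, an optional YAML/JSON config file, and explicit
#' overrides (in that order of increasing precedence) into a [sim_config()]
#' plus evaluation settings.  The resolved configuration round-trips through
#' serialization unchanged and is echoed into every report.
#'
#' @param path optional YAML (`.yaml`/`.yml`) or JSON config file.
#' @param overrides named list of values overriding the file.
#' @return list with elements `sim` (a `sim_config`), `cutoffs`,
#'   `true_top_fraction`, `false_bottom_fraction`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    n_features = 30000L, n_per_group = c(5L, 5L), frac_zero_de = 0.05,
    phi_filter = c(0, 5), low_expr_weight_exponent = 1,
    libsize_range = c(5e6, 4e7), n_reps = 3L, seed = 1L,
    cutoffs = c(0.01, 0.05, 0.1),
    true_top_fraction = 0.40, false_bottom_fraction = 0.20
  )
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop(sprintf("I/O error: cannot read config '%s'", path), call. = FALSE)
    }
    parsed <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
    cfg <- modifyList(cfg, parsed)
  }
  cfg <- modifyList(cfg, overrides[!vapply(overrides, is.null, logical(1))])
  list(sim = sim_config(n_features = cfg$n_features,
                        n_per_group = cfg$n_per_group,
                        frac_zero_de = cfg$frac_zero_de,
                        phi_filter = cfg$phi_filter,
                        low_expr_weight_exponent = cfg$low_expr_weight_exponent,
                        libsize_range = cfg$libsize_range,
                        n_reps = cfg$n_reps, seed = cfg$seed),
       cutoffs = cfg$cutoffs,
       true_top_fraction = cfg$true_top_fraction,
       false_bottom_fraction = cfg$false_bottom_fraction)
}

#' Serialize a benchmark report to JSON
#'
#' Writes per-method pooled AUC and FDR performance together with the fully
#' resolved configuration and seed, sufficient to regenerate the run.
#'
#' @param report a `benchmark_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    seed = report$seed,
    config = report$config,
    pooled = lapply(report$pooled, function(x) {
      list(auc = x$roc$auc, marker = x$roc$marker,
           fdr_performance = x$fdr_performance)
    }),
    scale_auc = if (!is.null(report$scale_roc)) {
      lapply(report$scale_roc, function(sc) {
        lapply(sc, function(r) if (is.null(r)) NULL else r$auc)
      })
    }
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
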