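# internal helpers: validation, seed substreams, logging

log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Set the logging threshold
#'
#' Messages below `level` are suppressed for the current session.
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return the previous level, invisibly.
#' @export
set_log_level <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  old <- getOption("zeroinone.log_level", "info")
  options(zeroinone.log_level = level)
  invisible(old)
}

zio_log <- function(level, fmt, ...) {
  thr <- log_levels[[getOption("zeroinone.log_level", "info")]]
  if (log_levels[[level]] >= thr) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
  invisible(NULL)
}

#' Derive a stage-specific random seed from a global seed
#'
#' Deterministically maps `(seed, stage)` to a 32-bit integer seed so that
#' pipeline stages can be re-run in isolation with stable randomness.
#'
#' @param seed integer global seed.
#' @param stage character tag naming the stage.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stage), length(stage) == 1L)
  ch <- utf8ToInt(stage)
  h <- sum(ch * seq_along(ch) * 131)
  as.integer((abs(seed) %% 2147483647 * 69069 + h) %% 2147483647)
}

assert_count_matrix <- function(counts, allow_real = FALSE) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("invalid-input: counts must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(counts))) {
    stop("invalid-input: counts must carry gene IDs as rownames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("schema error: duplicated gene IDs", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("invalid-input: counts must be finite and non-negative", call. = FALSE)
  }
  if (!allow_real && any(counts != floor(counts))) {
    stop("schema error: counts must be integers", call. = FALSE)
  }
  invisible(counts)
}

# design: factor (or coercible) of length ncol(counts) with exactly 2 levels
assert_design <- function(design, counts = NULL) {
  design <- as.factor(design)
  design <- droplevels(design)
  if (nlevels(design) != 2L) {
    stop("invalid-design: exactly two groups are required", call. = FALSE)
  }
  if (!is.null(counts) && length(design) != ncol(counts)) {
    stop("invalid-design: design length must equal the number of samples",
         call. = FALSE)
  }
  design
}

# per-gene zero pattern: "none", "both", or the level name of the single
# all-zero condition
zero_condition <- function(counts, design) {
  design <- assert_design(design, counts)
  lv <- levels(design)
  zA <- rowSums(counts[, design == lv[1], drop = FALSE]) == 0
  zB <- rowSums(counts[, design == lv[2], drop = FALSE]) == 0
  out <- rep("none", nrow(counts))
  out[zA & !zB] <- lv[1]
  out[!zA & zB] <- lv[2]
  out[zA & zB] <- "both"
  names(out) <- rownames(counts)
  out
}
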