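# Small in-code fixtures shared across test files.

toy_design <- function(nA = 3, nB = 4) factor(rep(c("A", "B"), c(nA, nB)))

# gene x sample matrix of NB counts at a fixed mean/dispersion
nb_toy_counts <- function(n_genes, mu, phi, nA = 5, nB = 5, seed = 1,
                          libsizes = NULL) {
  set.seed(seed)
  ns <- nA + nB
  m <- if (is.null(libsizes)) matrix(mu, n_genes, ns) else {
    outer(rep(mu, n_genes), libsizes / mean(libsizes))
  }
  counts <- if (phi > 0) {
    matrix(rnbinom(n_genes * ns, mu = as.vector(m), size = 1 / phi),
           n_genes, ns)
  } else {
    matrix(rpois(n_genes * ns, lambda = as.vector(m)), n_genes, ns)
  }
  dimnames(counts) <- list(sprintf("g%04d", seq_len(n_genes)),
                           c(paste0("A", seq_len(nA)), paste0("B", seq_len(nB))))
  storage.mode(counts) <- "integer"
  counts
}

small_sim <- function(n_features = 800, seed = 3, frac = 0.05, n_pool = 3000,
                      exponent = 1) {
  cfg <- sim_config(n_features = n_features, frac_zero_de = frac,
                    low_expr_weight_exponent = exponent, n_reps = 1,
                    seed = seed)
  pool <- make_surrogate_pool(n_pool, seed = seed + 1)
  list(cfg = cfg, pool = pool,
       null = simulate_null_counts(pool, cfg))
}
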