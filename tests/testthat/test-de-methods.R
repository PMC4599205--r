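test_that("moment dispersion estimation behaves at its endpoints", {
  # Poisson data: moment estimates are near zero after shrinkage
  m <- nb_toy_counts(5000, mu = 200, phi = 0, nA = 5, nB = 5, seed = 19)
  des <- toy_design(5, 5)
  disp <- estimate_dispersions(m, des)
  expect_lt(median(disp$phi_shrunk), 0.05)

  # constant counts within groups: variance 0 < mean forces the clamp
  cm <- matrix(rep(c(10L, 10L, 10L, 40L, 40L, 40L), 3), 3, 6, byrow = TRUE,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:6)))
  d2 <- estimate_dispersions(cm, toy_design(3, 3))
  expect_true(all(d2$phi_moment == 0))

  # shrink weight 1 collapses onto the trend
  d3 <- estimate_dispersions(m[1:500, ], des, shrink_weight = 1)
  expect_equal(d3$phi_shrunk, d3$phi_trend)
  # and the shrunk value always lies between moment and trend
  d4 <- estimate_dispersions(m[1:500, ], des, shrink_weight = 0.3)
  lo <- pmin(d4$phi_moment, d4$phi_trend)
  hi <- pmax(d4$phi_moment, d4$phi_trend)
  expect_true(all(d4$phi_shrunk >= lo - 1e-12 & d4$phi_shrunk <= hi + 1e-12))

  expect_error(estimate_dispersions(cm, factor(c("A", rep("B", 5)))),
               "invalid-design")
})

test_that("single-condition dispersion basis uses only the non-zero condition", {
  s <- small_sim(n_features = 500, seed = 51)
  out <- introduce_zeros(s$null, s$cfg)
  ds <- estimate_dispersions(out$counts, out$design,
                             basis = "single-nonzero-condition")
  zc <- zeroinone:::zero_condition(out$counts, out$design)
  expect_setequal(ds$gene_id, names(zc)[zc %in% levels(out$design)])
  expect_true(all(ds$basis == "single-nonzero-condition"))
})

test_that("exact NB test matches exhaustive enumeration and the binomial identity", {
  # enumeration oracle across totals and dispersions, equal group sizes
  for (phi in c(0, 0.1, 0.5)) {
    for (s in c(1, 2, 7, 30, 60)) {
      for (sa in unique(c(0, 1, s %/% 3, s %/% 2, s))) {
        expect_equal(zeroinone:::exact_nb_pvalue(sa, s, 5, 5, phi),
                     nb_doubletail_oracle(sa, s, 5, 5, phi),
                     tolerance = 1e-10)
      }
    }
  }

  # phi = 0, equal group sizes: identical to the two-sided exact binomial
  for (s in c(5, 12, 30, 50)) {
    for (sa in c(0, 2, s %/% 2)) {
      expect_equal(zeroinone:::exact_nb_pvalue(sa, s, 4, 4, 0),
                   binom.test(sa, s, 0.5)$p.value, tolerance = 1e-10)
    }
  }

  # symmetric split at the conditional mode -> P = 1
  expect_equal(zeroinone:::exact_nb_pvalue(15, 30, 5, 5, 0.1), 1)
  expect_equal(zeroinone:::exact_nb_pvalue(0, 0, 5, 5, 0.3), 1)
})

test_that("exact NB test agrees with the Bioconductor double-tail test", {
  set.seed(61)
  n <- 200
  y <- matrix(rnbinom(n * 10, mu = 80, size = 1 / 0.15), n, 10,
              dimnames = list(sprintf("g%03d", 1:n), paste0("s", 1:10)))
  # equalize library sizes exactly so no count adjustment happens anywhere
  target <- 1e5L
  for (j in 1:10) {
    extra <- target - colSums(y)[j]
    stopifnot(extra > 0)
    y <- rbind(y, 0L)
    y[n + j, j] <- as.integer(extra)
  }
  rownames(y)[n + 1:10] <- paste0("filler", 1:10)
  storage.mode(y) <- "integer"
  des <- toy_design(5, 5)
  disp <- estimate_dispersions(y, des)
  disp$phi_shrunk <- rep(0.15, nrow(y))
  ours <- exact_nb_test(y, des, disp, factors = rep(1, 10))
  ref <- edgeR::exactTestDoubleTail(y[, 1:5], y[, 6:10], dispersion = 0.15)
  expect_lt(max(abs(ours$pvalue[1:n] - ref[1:n])), 1e-6)
})

test_that("DE evidence is monotone in the expressed-condition signal", {
  # zero-in-one-condition genes with increasing counts opposite: P decreases
  mu_levels <- c(2, 8, 32, 128, 512)
  m <- matrix(0L, 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  set.seed(71)
  for (i in seq_along(mu_levels)) {
    m[i, 6:10] <- as.integer(rpois(5, mu_levels[i]) + 1L)
  }
  # embed in a realistic expressed background so the variance trend and the
  # prior are estimated sensibly
  bg <- nb_toy_counts(300, mu = 200, phi = 0.1, nA = 5, nB = 5, seed = 72)
  rownames(bg) <- paste0("bg", 1:300)
  mm <- rbind(m, bg)
  des <- toy_design(5, 5)
  disp <- estimate_dispersions(mm, des)
  disp$phi_shrunk <- rep(0.1, nrow(mm))
  nb <- exact_nb_test(mm, des, disp, factors = rep(1, 10))
  expect_true(all(diff(nb$pvalue[1:5]) <= 0))

  # the moderated t is subject to per-gene variance noise, so assert a
  # strong rank trend rather than per-draw strict monotonicity
  f <- tmm_factors(mm)
  mt <- moderated_t_test(log_cpm(cpm(mm, f)), des, mm)
  expect_gt(cor(seq_along(mu_levels), -log10(mt$pvalue[1:5]),
                method = "spearman"), 0.8)
})

test_that("both surrogate tests control type-I error on a pure-null simulation", {
  cfg <- sim_config(n_features = 5000, frac_zero_de = 0, seed = 81)
  pool <- make_surrogate_pool(20000, seed = 82)
  sim <- simulate_null_counts(pool, cfg)
  f <- tmm_factors(sim$counts)
  nb <- exact_nb_test(sim$counts, sim$design, factors = f)
  mt <- moderated_t_test(log_cpm(cpm(sim$counts, f)), sim$design, sim$counts)
  for (r in list(nb, mt)) {
    frac <- mean(r$pvalue < 0.05)
    expect_gte(frac, 0.035)
    expect_lte(frac, 0.065)
  }
})

test_that("moderated t handles exact ties and null coefficients", {
  # identical group means -> t = 0, P = 1
  vals <- rbind(flat = c(3, 4, 5, 3, 4, 5),
                de = c(1, 1.2, 0.8, 6, 6.3, 5.9),
                noise = c(2, 3, 2.5, 2.2, 2.9, 2.4))
  colnames(vals) <- paste0("s", 1:6)
  nm <- zeroinone:::new_norm_matrix(vals, "log-cpm", rep(1, 6), rep(1e6, 6))
  mt <- moderated_t_test(nm, toy_design(3, 3))
  expect_equal(mt$t[mt$gene_id == "flat"], 0)
  expect_equal(mt$pvalue[mt$gene_id == "flat"], 1)
  expect_lt(mt$pvalue[mt$gene_id == "de"], 0.05)

  expect_error(moderated_t_test(nm, factor(c("A", rep("B", 5)))),
               "invalid-design")
})

test_that("variance-prior moment matching matches the limma estimator", {
  set.seed(91)
  d <- 8
  s2 <- 0.05 * rf(2000, d, 6)
  ours <- zeroinone:::fit_var_prior(s2, d)
  ref <- limma::fitFDist(s2, df1 = d)
  expect_equal(ours$d0, ref$df2, tolerance = 1e-6)
  expect_equal(ours$s02, ref$scale, tolerance = 1e-6)

  # identical variances: infinite prior df, prior variance = the common value
  ours0 <- zeroinone:::fit_var_prior(rep(0.2, 100), d)
  expect_identical(ours0$d0, Inf)
  expect_equal(ours0$s02, 0.2, tolerance = 1e-9)
  ref0 <- limma::fitFDist(rep(0.2, 100), df1 = d)
  expect_identical(ref0$df2, Inf)
  expect_equal(ours0$s02, ref0$scale, tolerance = 1e-9)
})

test_that("BH adjustment follows the step-up closed form and permutation equivariance", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.17), 0.17)
  expect_error(adjust_bh(c(0.5, 1.2)), "invalid-input")
  expect_error(adjust_bh(c(-0.1, 0.5)), "invalid-input")

  set.seed(101)
  p <- runif(50)
  fdr <- adjust_bh(p)
  perm <- sample(50)
  expect_equal(adjust_bh(p[perm]), fdr[perm])
  # monotone in the p-value ranking
  expect_true(all(diff(fdr[order(p)]) >= 0))
})

test_that("external result tables are validated and completed", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene_id = c("a", "b"), pvalue = c(0.01, 0.5),
                         fdr = c(0.02, 0.5)),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  res <- load_external_results(f)
  expect_equal(res$pvalue, c(0.01, 0.5))
  expect_equal(res$fdr, c(0.02, 0.5))
  expect_equal(res$method, c("external", "external"))

  write.table(data.frame(gene_id = c("a", "b"), pvalue = c(0.01, 0.5)),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  res2 <- load_external_results(f)
  expect_equal(res2$fdr, adjust_bh(c(0.01, 0.5)))

  write.table(data.frame(gene_id = "a", pvalue = 1.2),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_external_results(f), "invalid-input")

  write.table(data.frame(id = "a", p = 0.1),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_external_results(f), "schema")
  # but configurable column names recover it
  res3 <- load_external_results(f, id_col = "id", p_col = "p",
                                method = "edger")
  expect_equal(res3$method, "edger")

  # published FDR columns flow through the adapter
  res4 <- load_external_results(
    system.file("extdata", "encode_zero_gene_table.tsv", package = "zeroinone"),
    p_col = "edger_fdr", fdr_col = "edger_fdr", method = "edger-published")
  expect_equal(nrow(res4), 20)
})

test_that("zeroing one condition does not drastically shift dispersion estimates", {
  cfg <- sim_config(n_features = 3000, seed = 111)
  pool <- make_surrogate_pool(10000, seed = 112)
  null <- simulate_null_counts(pool, cfg)
  out <- introduce_zeros(null, cfg)
  diag <- dispersion_shift_diagnostic(out$counts, out$design, out$truth,
                                      original_counts = null$counts)
  expect_equal(nrow(diag), sum(out$truth$label == "true"))
  # same NB law estimated from 5 vs 10 replicates: no drastic reduction —
  # the medians agree within a factor of 2 (the clamped moment estimator is
  # more often zero at 5 replicates, so exact agreement is not expected)
  med_s <- median(diag$phi_single)
  med_b <- median(diag$phi_both)
  expect_gt(med_s, med_b / 2)
  expect_lt(med_s, med_b * 2)

  # Poisson truth: both estimates near zero
  cfgp <- sim_config(n_features = 1500, seed = 113)
  poolp <- zeroinone:::new_param_pool(10^runif(2000, 1, 3), rep(0, 2000),
                                      "parametric-surrogate")
  nullp <- simulate_null_counts(poolp, cfgp)
  outp <- introduce_zeros(nullp, cfgp)
  diagp <- dispersion_shift_diagnostic(outp$counts, outp$design, outp$truth,
                                       original_counts = nullp$counts)
  expect_lt(median(diagp$phi_single), 0.05)
  expect_lt(median(diagp$phi_both), 0.05)

  # empty truth -> empty table
  et <- out$truth; et$label <- "false"
  expect_equal(nrow(dispersion_shift_diagnostic(out$counts, out$design, et)), 0)
})
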