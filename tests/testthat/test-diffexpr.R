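test_that("constant identical groups give t = 0 and p = 1 for every gene", {
  expr <- matrix(5, nrow = 6, ncol = 8,
                 dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:8)))
  meta <- data.frame(sample_id = colnames(expr), patient_id = colnames(expr),
                     group = rep(c("case", "control"), each = 4))
  res <- suppressMessages(fit_moderated_t(expr, meta))
  expect_equal(res$t, rep(0, 6))
  expect_equal(res$p_value, rep(1, 6))
})

test_that("moderated t matches the straight-line formula oracle", {
  fx <- make_de_fixture(n_genes = 10, n1 = 4, n2 = 4, seed = 42)
  res <- fit_moderated_t(fx$expr, fx$meta)
  orc <- moderated_t_oracle(fx$expr[, fx$meta$group == "case"],
                            fx$expr[, fx$meta$group == "control"])
  expect_true(is.finite(attr(res, "df_prior")))
  expect_equal(res$t, unname(orc$t), tolerance = 1e-8)
  expect_equal(res$p_value, unname(orc$p), tolerance = 1e-8)
  expect_equal(res$s2_post, unname(orc$s2_post), tolerance = 1e-8)
  expect_equal(attr(res, "df_prior"), orc$df_prior, tolerance = 1e-6)
})

test_that("moderated t agrees with limma's empirical-Bayes fit", {
  fx <- make_de_fixture(n_genes = 50, n1 = 5, n2 = 5, seed = 7)
  res <- fit_moderated_t(fx$expr, fx$meta)
  design <- cbind(control = 1, case_vs_control = fx$meta$group == "case")
  efit <- limma::eBayes(limma::lmFit(fx$expr, design))
  expect_equal(res$t, unname(efit$t[, "case_vs_control"]), tolerance = 1e-6)
  expect_equal(res$s2_post, unname(efit$s2.post), tolerance = 1e-6)
  expect_equal(attr(res, "df_prior"), efit$df.prior, tolerance = 1e-4)
})

test_that("homoscedastic data collapse to a common posterior variance", {
  set.seed(11)
  expr <- matrix(abs(rnorm(80 * 10, 8, 0.5)), 80, 10,
                 dimnames = list(sprintf("g%d", 1:80), sprintf("s%d", 1:10)))
  meta <- data.frame(sample_id = colnames(expr), patient_id = colnames(expr),
                     group = rep(c("case", "control"), each = 5))
  res <- suppressMessages(fit_moderated_t(expr, meta))
  if (is.infinite(attr(res, "df_prior"))) {
    expect_equal(length(unique(res$s2_post)), 1L)
  } else {
    # heavy shrinkage: posterior variances nearly constant
    expect_lt(diff(range(res$s2_post)) / mean(res$s2_post), 0.5)
  }
})

test_that("injecting a tiny prior df recovers the ordinary pooled t", {
  fx <- make_de_fixture(seed = 13)
  res <- fit_moderated_t(fx$expr, fx$meta, df_prior = 1e-10, s2_prior = 1)
  x1 <- fx$expr[, fx$meta$group == "case"]
  x2 <- fx$expr[, fx$meta$group == "control"]
  s2 <- (rowSums((x1 - rowMeans(x1))^2) + rowSums((x2 - rowMeans(x2))^2)) /
    (fx$n1 + fx$n2 - 2)
  t_ord <- (rowMeans(x1) - rowMeans(x2)) /
    sqrt(s2 * (1 / fx$n1 + 1 / fx$n2))
  expect_equal(res$t, unname(t_ord), tolerance = 1e-6)
})

test_that("swapping the contrast negates effects but keeps p-values", {
  fx <- make_de_fixture(seed = 21)
  a <- fit_moderated_t(fx$expr, fx$meta, c("case", "control"))
  b <- fit_moderated_t(fx$expr, fx$meta, c("control", "case"))
  expect_equal(a$mean_diff, -b$mean_diff)
  expect_equal(a$t, -b$t)
  expect_equal(a$p_value, b$p_value)
})

test_that("input errors are caught", {
  fx <- make_de_fixture(seed = 1)
  expect_error(fit_moderated_t(fx$expr, fx$meta, c("case", "treated")),
               "absent from metadata")
  expect_error(fit_moderated_t(fx$expr[, 1:3], fx$meta), "do not match")
})

test_that("Benjamini-Hochberg matches step-up enumeration on exhaustive cases", {
  expect_equal(benjamini_hochberg(0.05), 0.05)
  expect_equal(benjamini_hochberg(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(99)
  for (i in 1:25) {
    p <- round(runif(sample(1:10, 1)), 3)  # rounding induces ties
    adj <- benjamini_hochberg(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # monotone: ordering of raw p preserved in adjusted p
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(benjamini_hochberg(c(0.1, -0.1)), "\\[0, 1\\]")
})

test_that("DEG selection is thresholded, directional and ordered", {
  res <- data.frame(gene_id = c("b", "a", "c"),
                    mean_diff = c(1, -2, 0.5),
                    adj_p = c(0.05, 0.01, 0.5),
                    direction = c("up", "down", "up"))
  degs <- select_degs(res, alpha = 0.1)
  expect_equal(degs$gene_id, c("a", "b"))
  expect_equal(degs$direction, c("down", "up"))
  expect_equal(nrow(select_degs(transform(res, adj_p = 1), 0.1)), 0)
  wide <- select_degs(res, alpha = 0.6)
  expect_true(all(degs$gene_id %in% wide$gene_id))
  expect_error(select_degs(res, alpha = 0), "\\(0, 1\\)")
})

test_that("planted DE genes are recovered cleanly in a strong-signal regime", {
  # Sensitivity is perfect, and every planted gene gets its planted sign.
  # BH at level 0.1 controls the false-discovery *rate*, not the count, so a
  # discovery set this large is expected to include ~10% null genes; the
  # false-discovery proportion is bounded accordingly rather than at zero.
  for (seed in 1:5) {
    cfg <- sim_config(n_genes = 100, n_cases = 20, n_controls = 20,
                      de_effect = 3, noise_sd = 0.1, seed = seed)
    sim <- generate_cross_sectional(cfg)
    res <- suppressMessages(fit_moderated_t(sim$expr, sim$meta))
    degs <- select_degs(res, 0.1)
    planted <- c(sim$truth$de_up, sim$truth$de_down)
    expect_length(setdiff(planted, degs$gene_id), 0)  # sensitivity 1.0
    hits_up <- intersect(degs$gene_id[degs$direction == "up"], planted)
    hits_down <- intersect(degs$gene_id[degs$direction == "down"], planted)
    expect_setequal(hits_up, sim$truth$de_up)
    expect_setequal(hits_down, sim$truth$de_down)
    fdp <- length(setdiff(degs$gene_id, planted)) / nrow(degs)
    expect_lte(fdp, 0.2)
  }
})

test_that("raw p-values are calibrated under the null", {
  hits <- 0L; total <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(n_genes = 50, de_fraction = 0, seed = seed)
    sim <- generate_cross_sectional(cfg)
    res <- suppressMessages(fit_moderated_t(sim$expr, sim$meta))
    hits <- hits + sum(res$p_value < 0.05)
    total <- total + nrow(res)
  }
  expect_gte(hits / total, 0.03)
  expect_lte(hits / total, 0.07)
})
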