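test_that("Kruskal-Wallis reproduces the worked three-group example", {
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(kw$H, 32 / 7, tolerance = 1e-12)
  expect_equal(kw$p, pchisq(32 / 7, df = 2, lower.tail = FALSE))
  expect_equal(kw$p, 0.1017, tolerance = 1e-3)
})

test_that("all-tied input returns H = 0, p = 1 by convention", {
  kw <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(kw$H, 0)
  expect_equal(kw$p, 1)
})

test_that("the statistic is invariant under strictly increasing transforms", {
  set.seed(5)
  for (i in 1:10) {
    groups <- lapply(1:4, function(k) sample(1:8, 5, replace = TRUE))
    a <- kruskal_wallis(groups)
    b <- kruskal_wallis(lapply(groups, function(v) exp(v) + 3))
    expect_equal(a$H, b$H, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
  }
})

test_that("the tie-corrected rank formula oracle agrees with the test", {
  set.seed(17)
  for (i in 1:15) {
    groups <- lapply(1:3, function(k) sample(1:6, sample(3:7, 1), replace = TRUE))
    if (length(unique(unlist(groups))) == 1) next
    kw <- kruskal_wallis(groups)
    orc <- kw_oracle(groups)
    expect_equal(kw$H, orc$H, tolerance = 1e-10)
    expect_equal(kw$p, orc$p, tolerance = 1e-10)
  }
})

test_that("kruskal_wallis validates its input", {
  expect_error(kruskal_wallis(list(c(1, 2))), "at least two")
  expect_error(kruskal_wallis(list(c(1, 2), numeric(0))), "at least one value")
  expect_error(kruskal_wallis(list(1, 2)), "at least 3 values")
})

test_that("monotone_pattern implements the non-strict chains with tie handling", {
  expect_equal(monotone_pattern(c(1, 2, 3, 4, 5)), "MIE")
  expect_equal(monotone_pattern(c(5, 4, 4, 3, 1)), "MDE")
  expect_equal(monotone_pattern(c(1, 3, 2, 4, 5)), "none")
  expect_equal(monotone_pattern(c(2, 2, 2, 2, 2)), "none")
  expect_equal(monotone_pattern(c(1, 1, 1, 1, 2)), "MIE")
  # epsilon-tolerant: small dips within epsilon do not break the chain
  expect_equal(monotone_pattern(c(1, 1.9, 1.85, 3), epsilon = 0.1), "MIE")
  expect_error(monotone_pattern(c(1, NA, 2)), "finite")
  expect_error(monotone_pattern(1), "at least two")
})

test_that("reversing a profile swaps MIE and MDE and fixes none", {
  set.seed(23)
  for (i in 1:50) {
    m <- round(runif(5, 0, 3), 1)
    a <- monotone_pattern(m)
    b <- monotone_pattern(rev(m))
    expected <- c(MIE = "MDE", MDE = "MIE", none = "none")[[a]]
    expect_equal(b, expected)
  }
})

make_long_fixture <- function(seed = 1, trend_step = 0.5, noise_sd = 0.5,
                              n_genes = 60) {
  cfg <- sim_config(n_genes = n_genes, trend_step = trend_step,
                    noise_sd = noise_sd, seed = seed)
  generate_longitudinal(cfg)
}

test_that("a noiseless increasing gene dominates the screen", {
  sim <- make_long_fixture(seed = 3, noise_sd = 0)
  up <- sim$truth$monotone_up$responder
  scr <- screen_genes(sim$expr, sim$meta, "responder")
  expect_true(all(scr$p_value[scr$gene_id %in% up] <=
                  min(scr$p_value[!scr$gene_id %in%
                                  c(up, sim$truth$monotone_down$responder)])))
  expect_true(all(scr$H >= 0))
})

test_that("a flat simulation flags few genes", {
  flagged <- 0L; total <- 0L
  for (seed in 1:10) {
    sim <- make_long_fixture(seed = seed, trend_step = 0)
    scr <- screen_genes(sim$expr, sim$meta, "responder")
    flagged <- flagged + sum(scr$flagged)
    total <- total + nrow(scr)
  }
  expect_lte(flagged / total, 0.2)
})

test_that("screening is gated: no KW hits means no MEGs", {
  sim <- make_long_fixture(seed = 4, trend_step = 0)
  scr <- screen_genes(sim$expr, sim$meta, "responder")
  scr$flagged <- FALSE
  megs <- find_megs(scr, sim$expr, sim$meta, "responder")
  expect_equal(nrow(megs), 0)
})

test_that("reversing the time order swaps MEG directions exactly", {
  sim <- make_long_fixture(seed = 6)
  scr <- screen_genes(sim$expr, sim$meta, "responder")
  fwd <- find_megs(scr, sim$expr, sim$meta, "responder")
  meta_rev <- sim$meta
  meta_rev$timepoint <- max(meta_rev$timepoint) - meta_rev$timepoint
  scr_rev <- screen_genes(sim$expr, meta_rev, "responder")
  rev <- find_megs(scr_rev, sim$expr, meta_rev, "responder")
  expect_equal(scr$H, scr_rev$H, tolerance = 1e-12)  # KW ignores order
  expect_setequal(fwd$gene_id, rev$gene_id)
  m <- match(fwd$gene_id, rev$gene_id)
  expect_true(all(fwd$meg_direction != rev$meg_direction[m]))
})

test_that("recovered MEGs are flagged genes with the planted direction", {
  sim <- make_long_fixture(seed = 8)
  for (g in c("responder", "nonresponder")) {
    scr <- screen_genes(sim$expr, sim$meta, g)
    megs <- find_megs(scr, sim$expr, sim$meta, g)
    expect_true(all(megs$gene_id %in% scr$gene_id[scr$flagged]))
    up_hits <- intersect(megs$gene_id, sim$truth$monotone_up[[g]])
    down_hits <- intersect(megs$gene_id, sim$truth$monotone_down[[g]])
    expect_true(all(megs$meg_direction[megs$gene_id %in% up_hits] == "up"))
    expect_true(all(megs$meg_direction[megs$gene_id %in% down_hits] == "down"))
  }
})

test_that("the Friedman option respects patient blocking and still finds trends", {
  sim <- make_long_fixture(seed = 9, noise_sd = 0.3)
  scr <- screen_genes(sim$expr, sim$meta, "responder", method = "friedman")
  planted <- c(sim$truth$monotone_up$responder, sim$truth$monotone_down$responder)
  expect_gt(mean(scr$flagged[scr$gene_id %in% planted]), 0.5)
})

test_that("group and timepoint requirements are enforced", {
  sim <- make_long_fixture(seed = 2)
  expect_error(screen_genes(sim$expr, sim$meta, "placebo"), "not present")
  meta_nt <- sim$meta; meta_nt$timepoint <- NULL
  expect_error(screen_genes(sim$expr, meta_nt, "responder"), "timepoint")
  expect_error(timepoint_means(sim$expr, sim$meta, "placebo"), "not present")
})
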