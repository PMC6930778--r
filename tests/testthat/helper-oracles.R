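# Independent oracles, deliberately coded straight from the defining
# formulas (no shared code with the package internals they check).

# Fixed-point iteration r <- (1 - d) * exp + d * W D^-1 r for the rank
# system; converges because the spectral radius of d W D^-1 is < 1.
jacobi_generank <- function(W, d, expr, tol = 1e-12, max_iter = 100000L) {
  W <- as.matrix(W)
  deg <- colSums(W)
  dinv <- ifelse(deg > 0, 1 / deg, 0)
  M <- W %*% diag(dinv, nrow = length(deg))
  r <- expr
  for (i in seq_len(max_iter)) {
    r_new <- (1 - d) * expr + d * as.numeric(M %*% r)
    if (max(abs(r_new - r)) < tol) return(r_new)
    r <- r_new
  }
  stop("Jacobi oracle failed to converge")
}

# Step-up FDR adjustment by direct enumeration over all j >= i.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, numeric(1))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# Kruskal-Wallis from the mid-rank formula with explicit tie correction.
kw_oracle <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- rank(x)
  sizes <- lengths(groups)
  gi <- rep.int(seq_along(groups), sizes)
  rbar <- tapply(r, gi, mean)
  H <- 12 / (N * (N + 1)) * sum(sizes * (rbar - (N + 1) / 2)^2)
  ties <- table(x)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  list(H = H, p = pchisq(H, length(groups) - 1, lower.tail = FALSE))
}

# Log-scale bisection inverse of the (strictly decreasing) trigamma.
trigamma_inv_bisect <- function(x, lo = 1e-8, hi = 1e8) {
  for (i in 1:300) {
    mid <- sqrt(lo * hi)
    if (trigamma(mid) > x) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

# Straight-line coding of the moderated two-sample t: pooled variances,
# moment-matched log-variance hyperparameters, posterior variance blend.
moderated_t_oracle <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  dg <- n1 + n2 - 2
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  md <- m1 - m2
  s2 <- (rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)) / dg
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  evar <- var(e) - trigamma(dg / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inv_bisect(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s02 + dg * s2) / (d0 + dg)
    df_total <- d0 + dg
  } else {
    d0 <- Inf
    s02 <- exp(mean(e))
    s2_post <- rep(s02, length(s2))
    df_total <- Inf
  }
  t <- md / sqrt(s2_post * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), df_total), s2_post = s2_post,
       df_prior = d0, s2_prior = s02)
}

# Heteroscedastic two-group fixture on the nonnegative log2 scale.
make_de_fixture <- function(n_genes = 10, n1 = 4, n2 = 4, seed = 42) {
  set.seed(seed)
  sds <- runif(n_genes, 0.2, 2)
  shift <- rnorm(n_genes, 0, 1)
  x1 <- matrix(rnorm(n_genes * n1, 8 + shift, sds), n_genes, n1)
  x2 <- matrix(rnorm(n_genes * n2, 8, sds), n_genes, n2)
  expr <- cbind(x1, x2)
  expr[expr < 0] <- 0
  rownames(expr) <- sprintf("g%02d", seq_len(n_genes))
  colnames(expr) <- c(sprintf("a%d", seq_len(n1)), sprintf("b%d", seq_len(n2)))
  meta <- data.frame(sample_id = colnames(expr),
                     patient_id = colnames(expr),
                     group = rep(c("case", "control"), c(n1, n2)),
                     stringsAsFactors = FALSE)
  list(expr = expr, meta = meta, n1 = n1, n2 = n2)
}

table1_path <- function() system.file("extdata", "table1_patients.tsv", package = "megrank")
table2_path <- function() system.file("extdata", "table2_megs.tsv", package = "megrank")

# Pooled planted-MEG recovery over one simulated pipeline run.
recovery_counts <- function(seed, trend_mode = "random") {
  cfg <- pipeline_config(
    sim = sim_config(seed = seed, trend_mode = trend_mode),
    out_dir = tempfile("rec_"))
  rep <- suppressMessages(run_pipeline(cfg))
  truth <- planted_truth(cfg$sim)
  megs <- read_tsv(file.path(cfg$out_dir, "megs_classified.tsv"))
  n_planted <- 0L; n_found <- 0L; n_dir_ok <- 0L
  for (g in c("responder", "nonresponder")) {
    for (dir in c("up", "down")) {
      planted <- truth[[paste0("monotone_", dir)]][[g]]
      n_planted <- n_planted + length(planted)
      hit <- megs$gene_id[megs$group == g]
      found <- intersect(planted, hit)
      n_found <- n_found + length(found)
      n_dir_ok <- n_dir_ok + sum(
        megs$meg_direction[megs$group == g][match(found, hit)] == dir)
    }
  }
  unlink(cfg$out_dir, recursive = TRUE)
  list(n_planted = n_planted, n_found = n_found, n_dir_ok = n_dir_ok,
       n_megs = nrow(megs))
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#", check.names = FALSE,
             stringsAsFactors = FALSE)
}
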