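#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around the standard step-up FDR adjustment:
#' for sorted p-values p_(1) <= ... <= p_(m), the adjusted value is
#' `min(1, min_{j >= i} m * p_(j) / j)`, mapped back to input order.
#'
#' @param raw_p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order as the input.
#' @export
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))
benjamini_hochberg <- function(raw_p) {
  if (!is.numeric(raw_p)) stop("p-values must be numeric", call. = FALSE)
  if (anyNA(raw_p) || any(raw_p < 0 | raw_p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(raw_p, method = "BH")
}

# Newton inversion of the trigamma function: solves trigamma(y) = x for
# y > 0. The iteration y <- y + dy with dy from the standard update on
# 1/trigamma converges globally and quadratically.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  repeat {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-10) break
  }
  y
}

# Moment-matching estimate of the scaled inverse-chi-square prior on gene
# variances: with z_g = log s_g^2, E[z] and Var[z] are matched to their
# digamma/trigamma expressions, and trigamma is inverted numerically.
# Genes with non-finite z (zero sample variance) are excluded from the
# moment estimates. Degenerate inputs (fewer than 4 usable genes, or excess
# variance of z not above its expected sampling value) fall back to
# d0 = Inf with a notice.
estimate_eb_hyperparams <- function(s2, df) {
  z <- log(s2)
  ok <- is.finite(z)
  fallback <- function(s02) {
    message("moderated t: variance prior degenerate; using d0 = Inf")
    if (!is.finite(s02)) s02 <- 0  # every gene variance-free
    list(df_prior = Inf, s2_prior = s02)
  }
  if (sum(ok) <= 3L) return(fallback(mean(s2[ok])))
  e <- z[ok] - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0)
    return(fallback(exp(emean)))
  df_prior <- 2 * trigamma_inverse(evar)
  s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  list(df_prior = df_prior, s2_prior = s2_prior)
}

#' Moderated two-sample t-tests with empirical-Bayes variance shrinkage
#'
#' For each gene, computes the pooled two-sample variance `s_g^2` on
#' `d_g = n1 + n2 - 2` residual degrees of freedom, estimates prior degrees
#' of freedom `d0` and prior variance `s0^2` by moment matching on
#' `log s_g^2`, forms the posterior variance
#' `s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, and tests the mean
#' difference (first contrast group minus second) with
#' `t = diff / (s~_g sqrt(1/n1 + 1/n2))` on `d0 + d_g` degrees of freedom.
#' When the observed spread of `log s_g^2` does not exceed its expected
#' sampling value the prior is degenerate (`d0 = Inf`) and all posterior
#' variances equal `s0^2`.
#'
#' @param expr nonnegative genes x samples matrix of log2 intensities with
#'   row and column names.
#' @param meta sample metadata data frame with columns `sample_id` and
#'   `group`, one row per expression column.
#' @param contrast character pair of group labels; the mean difference is
#'   `contrast[1] - contrast[2]` (by default case minus control, so "down"
#'   means underexpressed in cases).
#' @param method `"moderated"` (default) or `"plain"` for an unmoderated
#'   Welch t-test, provided for diagnostic comparison.
#' @param df_prior optional override of the estimated prior degrees of
#'   freedom (with `s2_prior`); mainly for methodological checks such as the
#'   `d0 -> 0` limit where the moderated t tends to the ordinary pooled t.
#' @param s2_prior optional override of the estimated prior variance.
#' @return a data frame with one row per gene: `gene_id`, `mean_diff`,
#'   `s2` (pooled variance), `df_resid`, `s2_post`, `t`, `df_total`,
#'   `p_value`, `adj_p` (Benjamini-Hochberg), and `direction`
#'   (`"up"` iff `mean_diff > 0`, ties broken to `"down"`).
#' @export
#' @examples
#' sim <- generate_cross_sectional(sim_config(n_genes = 40, seed = 2))
#' de <- fit_moderated_t(sim$expr, sim$meta, c("case", "control"))
#' head(de[order(de$adj_p), ])
fit_moderated_t <- function(expr, meta, contrast = c("case", "control"),
                            method = c("moderated", "plain"),
                            df_prior = NULL, s2_prior = NULL) {
  method <- match.arg(method)
  validate_expression(expr)
  validate_metadata(meta, expr)
  if (length(contrast) != 2L)
    stop("`contrast` must name exactly two groups", call. = FALSE)
  missing_grp <- setdiff(contrast, meta$group)
  if (length(missing_grp))
    stop("contrast group(s) absent from metadata: ",
         paste(missing_grp, collapse = ", "), call. = FALSE)
  idx1 <- meta$sample_id[meta$group == contrast[1]]
  idx2 <- meta$sample_id[meta$group == contrast[2]]
  n1 <- length(idx1); n2 <- length(idx2)
  if (n1 < 2L || n2 < 2L)
    stop("each contrast group needs at least 2 samples", call. = FALSE)

  x1 <- expr[, idx1, drop = FALSE]
  x2 <- expr[, idx2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  mean_diff <- m1 - m2
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  df_resid <- n1 + n2 - 2L
  s2 <- (ss1 + ss2) / df_resid

  if (method == "plain") {
    v1 <- ss1 / (n1 - 1L); v2 <- ss2 / (n2 - 1L)
    se2 <- v1 / n1 + v2 / n2
    tt <- mean_diff / sqrt(se2)
    df_w <- se2^2 / (v1^2 / (n1^2 * (n1 - 1L)) + v2^2 / (n2^2 * (n2 - 1L)))
    pv <- 2 * stats::pt(-abs(tt), df_w)
    res <- data.frame(gene_id = rownames(expr), mean_diff = mean_diff,
                      s2 = s2, df_resid = df_resid, s2_post = se2,
                      t = tt, df_total = df_w, p_value = pv,
                      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    if (is.null(df_prior) != is.null(s2_prior))
      stop("supply both or neither of `df_prior` and `s2_prior`", call. = FALSE)
    hyper <- if (is.null(df_prior)) estimate_eb_hyperparams(s2, df_resid)
             else list(df_prior = df_prior, s2_prior = s2_prior)
    s2_post <- if (is.infinite(hyper$df_prior)) {
      rep(hyper$s2_prior, length(s2))
    } else {
      (hyper$df_prior * hyper$s2_prior + df_resid * s2) /
        (hyper$df_prior + df_resid)
    }
    tt <- mean_diff / sqrt(s2_post * (1 / n1 + 1 / n2))
    tt[is.nan(tt) & mean_diff == 0] <- 0  # zero numerator over zero variance
    df_total <- hyper$df_prior + df_resid
    pv <- 2 * stats::pt(-abs(tt), df_total)
    res <- data.frame(gene_id = rownames(expr), mean_diff = mean_diff,
                      s2 = s2, df_resid = df_resid, s2_post = s2_post,
                      t = tt, df_total = df_total, p_value = pv,
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(res, "df_prior") <- hyper$df_prior
    attr(res, "s2_prior") <- hyper$s2_prior
  }
  res$adj_p <- benjamini_hochberg(res$p_value)
  res$direction <- ifelse(res$mean_diff > 0, "up", "down")
  res
}

#' Select differentially expressed genes
#'
#' Genes with BH-adjusted p-value below `alpha`, partitioned into up/down by
#' the sign of the mean difference and ordered by gene identifier.
#'
#' @param results data frame from [fit_moderated_t()].
#' @param alpha adjusted-p cutoff in (0, 1); default 0.1, a deliberately
#'   permissive value suited to small-sample screens feeding a downstream
#'   filter.
#' @return data frame with `gene_id`, `direction`, `mean_diff`, `adj_p`,
#'   sorted by `gene_id`.
#' @export
select_degs <- function(results, alpha = 0.1) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  keep <- results[results$adj_p < alpha,
                  c("gene_id", "direction", "mean_diff", "adj_p")]
  keep <- keep[order(keep$gene_id), ]
  rownames(keep) <- NULL
  keep
}
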