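#' Kruskal-Wallis test across time points
#'
#' Rank-based one-way comparison of `T >= 2` groups of values (here: the
#' weighted expression of one gene at each time point). Uses mid-ranks over
#' the pooled sample with the standard tie correction and the chi-square
#' approximation on `T - 1` degrees of freedom. An all-tied input (every
#' value identical) carries no ordering information and returns `H = 0`,
#' `p = 1` by convention.
#'
#' Because repeated measures from the same patients are pooled, this screen
#' ignores within-patient pairing; see [screen_genes()] for the paired
#' alternative.
#'
#' @param groups list of `T >= 2` non-empty numeric vectors.
#' @return list with elements `H` (statistic) and `p`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))  # H = 32/7
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("`groups` must be a list of at least two collections", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes == 0L))
    stop("every timepoint group must contain at least one value", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3L) stop("need at least 3 values in total", call. = FALSE)
  if (any(!is.finite(x))) stop("values must be finite", call. = FALSE)
  if (length(unique(x)) == 1L) return(list(H = 0, p = 1))
  g <- factor(rep.int(seq_along(groups), sizes))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Per-timepoint mean profile of weighted expression
#'
#' @param ranks genes x samples matrix of weighted expression (GeneRanks).
#' @param meta sample metadata with `sample_id`, `group`, `timepoint`.
#' @param group group label to profile.
#' @return genes x timepoints matrix of means, timepoints in ascending
#'   order of the declared category codes.
#' @export
timepoint_means <- function(ranks, meta, group) {
  sub <- meta[meta$group == group, ]
  if (!nrow(sub)) stop("group not present in metadata: ", group, call. = FALSE)
  if (is.null(sub$timepoint) || anyNA(sub$timepoint))
    stop("every sample of the group needs a timepoint", call. = FALSE)
  missing_s <- setdiff(sub$sample_id, colnames(ranks))
  if (length(missing_s))
    stop("samples absent from rank matrix: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  tps <- sort(unique(sub$timepoint))
  out <- sapply(tps, function(tp) {
    rowMeans(ranks[, sub$sample_id[sub$timepoint == tp], drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(ranks),
                dimnames = list(rownames(ranks), as.character(tps)))
  out
}

#' Screen genes for longitudinal differential expression
#'
#' One Kruskal-Wallis test per gene on that group's samples split by time
#' point, with Benjamini-Hochberg adjustment over exactly the genes tested
#' within the group (never pooled across groups). Genes with adjusted
#' p-value below `alpha` are flagged as longitudinally differentially
#' expressed.
#'
#' @inheritParams timepoint_means
#' @param alpha adjusted-p threshold in (0, 1); default 0.1.
#' @param method `"kruskal"` (default) pools repeated measures across
#'   patients, ignoring pairing; `"friedman"` blocks on patient
#'   (requires a complete patient x timepoint layout) and is offered as a
#'   sensitivity analysis that respects the repeated-measures structure.
#' @return data frame per gene: `gene_id`, `group`, `H`, `p_value`,
#'   `adj_p`, `flagged`.
#' @export
screen_genes <- function(ranks, meta, group, alpha = 0.1,
                         method = c("kruskal", "friedman")) {
  method <- match.arg(method)
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  sub <- meta[meta$group == group, ]
  if (!nrow(sub)) stop("group not present in metadata: ", group, call. = FALSE)
  if (is.null(sub$timepoint) || anyNA(sub$timepoint))
    stop("every sample of the group needs a timepoint", call. = FALSE)
  split_idx <- split(sub$sample_id, sub$timepoint)
  tests <- if (method == "friedman") {
    tp <- factor(sub$timepoint)
    blk <- factor(sub$patient_id)
    apply(ranks, 1, function(row) {
      ft <- stats::friedman.test(row[sub$sample_id], tp, blk)
      c(unname(ft$statistic), unname(ft$p.value))
    })
  } else {
    apply(ranks, 1, function(row) {
      kw <- kruskal_wallis(lapply(split_idx, function(s) row[s]))
      c(kw$H, kw$p)
    })
  }
  res <- data.frame(gene_id = rownames(ranks), group = group,
                    H = tests[1, ], p_value = tests[2, ],
                    stringsAsFactors = FALSE, row.names = NULL)
  res$adj_p <- benjamini_hochberg(res$p_value)
  res$flagged <- res$adj_p < alpha
  res
}

#' Classify a mean profile as monotone increasing, decreasing, or neither
#'
#' A profile is monotonically increasing (`"MIE"`) when every consecutive
#' difference is `>= -epsilon` and at least one exceeds `epsilon`;
#' monotonically decreasing (`"MDE"`) symmetric. The non-strict chains admit
#' ties, but an all-equal profile — which would satisfy both chains at once —
#' is classified `"none"`.
#'
#' @param means numeric vector of per-timepoint means (length >= 2).
#' @param epsilon tie tolerance >= 0; default 0.
#' @return one of `"MIE"`, `"MDE"`, `"none"`.
#' @export
#' @examples
#' monotone_pattern(c(1, 2, 3, 4, 5))  # "MIE"
#' monotone_pattern(c(5, 4, 4, 3, 1))  # "MDE"
#' monotone_pattern(c(2, 2, 2, 2, 2))  # "none"
monotone_pattern <- function(means, epsilon = 0) {
  if (length(means) < 2L) stop("need at least two timepoint means", call. = FALSE)
  if (any(!is.finite(means))) stop("means must be finite", call. = FALSE)
  if (epsilon < 0) stop("`epsilon` must be >= 0", call. = FALSE)
  d <- diff(means)
  if (all(d >= -epsilon) && any(d > epsilon)) return("MIE")
  if (all(d <= epsilon) && any(d < -epsilon)) return("MDE")
  "none"
}

#' Find monotonically expressed genes within a response group
#'
#' Applies [monotone_pattern()] to the per-timepoint mean weighted
#' expression of the genes that passed the Kruskal-Wallis screen (and only
#' those). MIE maps to direction `"up"`, MDE to `"down"`.
#'
#' @param screen data frame from [screen_genes()] for the same group.
#' @inheritParams timepoint_means
#' @param epsilon tie tolerance passed to [monotone_pattern()].
#' @return data frame per MEG: `gene_id`, `group`, `pattern`
#'   (`"MIE"`/`"MDE"`), `meg_direction` (`"up"`/`"down"`), sorted by gene.
#' @export
find_megs <- function(screen, ranks, meta, group, epsilon = 0) {
  if (!all(screen$group == group))
    stop("`screen` was computed for a different group", call. = FALSE)
  hits <- screen$gene_id[screen$flagged]
  empty <- data.frame(gene_id = character(0), group = character(0),
                      pattern = character(0), meg_direction = character(0),
                      stringsAsFactors = FALSE)
  if (!length(hits)) return(empty)
  means <- timepoint_means(ranks[hits, , drop = FALSE], meta, group)
  pattern <- apply(means, 1, monotone_pattern, epsilon = epsilon)
  keep <- pattern != "none"
  if (!any(keep)) return(empty)
  out <- data.frame(gene_id = hits[keep], group = group,
                    pattern = pattern[keep],
                    meg_direction = ifelse(pattern[keep] == "MIE", "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$gene_id), , drop = FALSE]
}
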