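#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generator. The defaults mirror
#' the study design the package targets: a cross-sectional case/control
#' contrast (26 cases vs. 18 controls), and a longitudinal arm with two
#' response groups of 9 patients each sampled at 5 ordered time points.
#' Effect sizes are on the log2-intensity scale throughout.
#'
#' Planted truth is drawn from a dedicated random substream derived from
#' `seed`, shared by [generate_cross_sectional()] and
#' [generate_longitudinal()]: the monotone-trend genes of each response group
#' are a subset of the planted differentially expressed (DE) genes, so a
#' simulated study is coherent end to end (every planted trend gene can in
#' principle survive the cross-sectional DEG filter).
#'
#' @param n_genes number of genes.
#' @param n_cases,n_controls cross-sectional sample sizes.
#' @param n_patients_per_group longitudinal patients per response group.
#' @param n_timepoints ordered time points per patient (>= 2).
#' @param de_fraction fraction of genes planted as cross-sectional DE.
#' @param de_effect log2 mean shift of planted DE genes in cases
#'   (up-genes `+de_effect`, down-genes `-de_effect`).
#' @param trend_step per-timepoint mean increment (log2 units) of planted
#'   monotone genes; `0` plants no trends.
#' @param noise_sd residual Gaussian standard deviation (log2 units).
#' @param baseline_mean nonnegative baseline log2 intensity. Keeping
#'   `baseline_mean - 6 * noise_sd >= 0` is recommended so that generated
#'   intensities stay nonnegative (the GeneRank precondition) without
#'   clipping.
#' @param edge_prob Erdos-Renyi edge probability of the interaction network.
#' @param isolated_fraction fraction of genes forced to degree 0.
#' @param trend_fraction fraction of the planted DE genes that receive a
#'   monotone trend in each response group.
#' @param trend_mode how trend directions relate to DE directions:
#'   `"random"` (independent coin flip), `"discordant"` (down-DE genes trend
#'   up and vice versa; the "good response" geometry), or `"concordant"`.
#' @param seed integer master seed; all generator substreams derive from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_study()], [generate_network()],
#'   [generate_cross_sectional()], [generate_longitudinal()]
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 50, seed = 7)
#' cfg$gene_ids[1:3]
sim_config <- function(n_genes = 200, n_cases = 26, n_controls = 18,
                       n_patients_per_group = 9, n_timepoints = 5,
                       de_fraction = 0.2, de_effect = 1, trend_step = 0.5,
                       noise_sd = 0.5, baseline_mean = 7, edge_prob = 0.02,
                       isolated_fraction = 0.1, trend_fraction = 0.5,
                       trend_mode = c("random", "discordant", "concordant"),
                       seed = 1L) {
  trend_mode <- match.arg(trend_mode)
  counts <- c(n_genes = n_genes, n_cases = n_cases, n_controls = n_controls,
              n_patients_per_group = n_patients_per_group)
  for (nm in names(counts)) {
    v <- counts[[nm]]
    if (length(v) != 1L || !is.finite(v) || v < 1 || v != round(v))
      stop(sprintf("`%s` must be a single positive integer", nm), call. = FALSE)
  }
  if (length(n_timepoints) != 1L || n_timepoints < 2 || n_timepoints != round(n_timepoints))
    stop("`n_timepoints` must be an integer >= 2", call. = FALSE)
  for (nm in c("de_fraction", "isolated_fraction", "trend_fraction")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop(sprintf("`%s` must be in [0, 1]", nm), call. = FALSE)
  }
  if (edge_prob < 0 || edge_prob > 1)
    stop("`edge_prob` must be in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (baseline_mean < 0) stop("`baseline_mean` must be >= 0", call. = FALSE)
  if (trend_step < 0) stop("`trend_step` must be >= 0", call. = FALSE)
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  if (baseline_mean - 6 * noise_sd < 0)
    warning("baseline_mean - 6 * noise_sd < 0: generated intensities may be clipped at 0")

  structure(list(
    n_genes = as.integer(n_genes), n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls),
    n_patients_per_group = as.integer(n_patients_per_group),
    n_timepoints = as.integer(n_timepoints),
    de_fraction = de_fraction, de_effect = de_effect,
    trend_step = trend_step, noise_sd = noise_sd,
    baseline_mean = baseline_mean, edge_prob = edge_prob,
    isolated_fraction = isolated_fraction, trend_fraction = trend_fraction,
    trend_mode = trend_mode, seed = as.integer(seed),
    gene_ids = sprintf("g%04d", seq_len(n_genes))
  ), class = "sim_config")
}

# Derived substream seeds: one master seed governs the whole simulated study,
# but each stage (network / cross-sectional / longitudinal / planted truth)
# gets its own stream so stages can be regenerated independently.
# Kept below 2^31 - 1.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483399 * 48271 + k * 16807) %% 2147483399)
}

stopifnot_config <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("`config` must be created with sim_config()", call. = FALSE)
}

#' Planted simulation truth
#'
#' Draws the planted cross-sectional DE gene sets and, per response group,
#' the planted monotone trend gene sets. Uses a dedicated substream of the
#' configuration seed, so cross-sectional and longitudinal generators called
#' separately agree on the truth.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `sim_truth` with character-vector fields `de_up`,
#'   `de_down` and per-group lists `monotone_up`, `monotone_down` (group
#'   names `responder`, `nonresponder`).
#' @export
planted_truth <- function(config) {
  stopifnot_config(config)
  set.seed(sub_seed(config$seed, 4L))
  n_de <- round(config$de_fraction * config$n_genes)
  de <- sort(sample(config$gene_ids, n_de))
  n_up <- ceiling(n_de / 2)
  de_up <- de[seq_len(n_up)]
  de_down <- setdiff(de, de_up)

  groups <- c("responder", "nonresponder")
  monotone_up <- monotone_down <- stats::setNames(
    rep(list(character(0)), length(groups)), groups)
  if (config$trend_step > 0 && n_de > 0) {
    n_tr <- round(config$trend_fraction * n_de)
    for (g in groups) {
      sel <- sort(sample(de, n_tr))
      up <- switch(config$trend_mode,
        random = as.logical(stats::rbinom(length(sel), 1L, 0.5)),
        discordant = sel %in% de_down,
        concordant = sel %in% de_up)
      monotone_up[[g]] <- sel[up]
      monotone_down[[g]] <- sel[!up]
    }
  }
  structure(list(de_up = de_up, de_down = de_down,
                 monotone_up = monotone_up, monotone_down = monotone_down),
            class = "sim_truth")
}

#' Generate a sparse undirected gene-interaction network
#'
#' Erdos-Renyi graph on the configured gene set with a forced isolated
#' subset: at least `ceiling(isolated_fraction * n_genes)` genes end with
#' degree 0, exercising the degree-0 branch of the GeneRank system. The
#' graph is simple (no self-loops, no multi-edges) and deterministic for a
#' fixed configuration seed.
#'
#' @param config a [sim_config()] object.
#' @return an undirected [igraph][igraph::igraph-package] graph whose vertex
#'   names are the configured gene identifiers.
#' @export
#' @examples
#' net <- generate_network(sim_config(n_genes = 30, seed = 1))
#' sum(igraph::degree(net) == 0) >= 3  # isolated_fraction default 0.1
generate_network <- function(config) {
  stopifnot_config(config)
  set.seed(sub_seed(config$seed, 1L))
  g <- igraph::sample_gnp(config$n_genes, config$edge_prob, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = config$gene_ids)
  n_iso <- ceiling(config$isolated_fraction * config$n_genes)
  if (n_iso > 0) {
    iso <- sample(config$gene_ids, n_iso)
    inc <- unlist(igraph::incident_edges(g, iso))
    if (length(inc)) g <- igraph::delete_edges(g, unique(inc))
  }
  g
}

clip_nonnegative <- function(values, what) {
  n_neg <- sum(values < 0)
  if (n_neg > 0) {
    warning(sprintf("%d %s intensities fell below 0 and were clipped", n_neg, what))
    values[values < 0] <- 0
  }
  values
}

#' Generate a cross-sectional case/control expression matrix
#'
#' Entries are `baseline_mean + group effect + N(0, noise_sd)`: planted
#' up-genes are shifted `+de_effect` in cases, down-genes `-de_effect`.
#' Values are clipped at 0 (with a warning) to respect the nonnegativity
#' precondition of GeneRank.
#'
#' @param config a [sim_config()] object.
#' @return a list with `expr` (genes x samples matrix), `meta` (data frame
#'   with `sample_id`, `patient_id`, `group`), and `truth`
#'   (see [planted_truth()]).
#' @export
generate_cross_sectional <- function(config) {
  stopifnot_config(config)
  truth <- planted_truth(config)
  set.seed(sub_seed(config$seed, 2L))
  case_ids <- sprintf("case_%02d", seq_len(config$n_cases))
  ctrl_ids <- sprintf("ctrl_%02d", seq_len(config$n_controls))
  samples <- c(case_ids, ctrl_ids)
  mu <- matrix(config$baseline_mean, config$n_genes, length(samples),
               dimnames = list(config$gene_ids, samples))
  mu[truth$de_up, case_ids] <- mu[truth$de_up, case_ids] + config$de_effect
  mu[truth$de_down, case_ids] <- mu[truth$de_down, case_ids] - config$de_effect
  expr <- mu + matrix(stats::rnorm(length(mu), sd = config$noise_sd),
                      nrow(mu), ncol(mu))
  expr <- clip_nonnegative(expr, "cross-sectional")
  meta <- data.frame(
    sample_id = samples, patient_id = samples,
    group = rep(c("case", "control"), c(config$n_cases, config$n_controls)),
    stringsAsFactors = FALSE)
  list(expr = expr, meta = meta, truth = truth)
}

#' Generate a longitudinal two-group expression matrix
#'
#' One column per (patient, timepoint) over two response groups. For a
#' planted monotone-up gene of a group, the population mean at timepoint `k`
#' (`k = 0 .. n_timepoints - 1`) is `baseline_mean + k * trend_step`;
#' monotone-down genes decrease analogously; all other genes are flat.
#' Time enters as an ordered index: the real sampling times the design
#' emulates are unevenly spaced but are analysed only as ordered categories.
#'
#' @param config a [sim_config()] object.
#' @return a list with `expr`, `meta` (columns `sample_id`, `patient_id`,
#'   `group`, `timepoint`), and `truth`.
#' @export
generate_longitudinal <- function(config) {
  stopifnot_config(config)
  truth <- planted_truth(config)
  set.seed(sub_seed(config$seed, 3L))
  groups <- c("responder", "nonresponder")
  prefix <- c(responder = "R", nonresponder = "N")
  meta <- do.call(rbind, lapply(groups, function(g) {
    patients <- sprintf("%s%02d", prefix[[g]], seq_len(config$n_patients_per_group))
    expand.grid(patient_id = patients,
                timepoint = seq_len(config$n_timepoints) - 1L,
                stringsAsFactors = FALSE)[, c("patient_id", "timepoint")] |>
      transform(group = g)
  }))
  meta$sample_id <- sprintf("%s_t%d", meta$patient_id, meta$timepoint)
  meta <- meta[order(meta$group == "nonresponder", meta$patient_id, meta$timepoint),
               c("sample_id", "patient_id", "group", "timepoint")]
  rownames(meta) <- NULL

  mu <- matrix(config$baseline_mean, config$n_genes, nrow(meta),
               dimnames = list(config$gene_ids, meta$sample_id))
  for (g in groups) {
    for (dir in c("up", "down")) {
      genes <- truth[[paste0("monotone_", dir)]][[g]]
      if (!length(genes)) next
      sgn <- if (dir == "up") 1 else -1
      cols <- meta$group == g
      step <- sgn * config$trend_step * meta$timepoint[cols]
      mu[genes, cols] <- mu[genes, cols] +
        matrix(step, length(genes), sum(cols), byrow = TRUE)
    }
  }
  expr <- mu + matrix(stats::rnorm(length(mu), sd = config$noise_sd),
                      nrow(mu), ncol(mu))
  expr <- clip_nonnegative(expr, "longitudinal")
  list(expr = expr, meta = meta, truth = truth)
}

#' Simulate a complete study
#'
#' Convenience wrapper producing the coherent triple used by
#' [run_pipeline()]: interaction network, cross-sectional case/control data
#' and longitudinal two-group data, all driven by one configuration seed via
#' independent substreams.
#'
#' @param config a [sim_config()] object.
#' @return a list with `network`, `cross` and `long`
#'   (each as returned by the respective generator) and `truth`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_genes = 50, seed = 3))
#' dim(study$long$expr)
simulate_study <- function(config) {
  stopifnot_config(config)
  list(network = generate_network(config),
       cross = generate_cross_sectional(config),
       long = generate_longitudinal(config),
       truth = planted_truth(config))
}
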