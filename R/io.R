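#' @name megrank-io
#' @title TSV readers and writers
#'
#' @description
#' All tables are tab-separated with a header row; writers prepend comment
#' lines (`#`-prefixed) carrying package version, seed and thresholds so
#' every output records its provenance, and format numbers at full
#' `%.17g` precision so write-then-read round-trips are lossless.
#' Readers validate identifiers (duplicate-free), numeric cells, and the
#' nonnegativity precondition required by the GeneRank stage.
NULL

validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(expr)))
    stop("duplicated gene identifiers in expression matrix", call. = FALSE)
  if (anyDuplicated(colnames(expr)))
    stop("duplicated sample identifiers in expression matrix", call. = FALSE)
  if (anyNA(expr) || any(!is.finite(expr)))
    stop("expression matrix contains missing or non-finite values", call. = FALSE)
  if (any(expr < 0)) {
    idx <- which(expr < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative expression value at gene %s, sample %s",
                 rownames(expr)[idx[1]], colnames(expr)[idx[2]]), call. = FALSE)
  }
  invisible(expr)
}

validate_metadata <- function(meta, expr = NULL) {
  req <- c("sample_id", "patient_id", "group")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("metadata missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(meta$sample_id))
    stop("duplicated sample identifiers in metadata", call. = FALSE)
  if (!is.null(expr)) {
    if (!setequal(meta$sample_id, colnames(expr)) ||
        nrow(meta) != ncol(expr))
      stop("metadata samples and expression columns do not match", call. = FALSE)
  }
  invisible(meta)
}

fmt_num <- function(x) sprintf("%.17g", x)

format_table <- function(df) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  out
}

write_tsv_table <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(format_table(df), con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_table <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write an expression matrix as TSV
#'
#' First column `gene_id`, remaining columns one per sample.
#'
#' @param expr genes x samples numeric matrix with dimnames.
#' @param path output file path.
#' @param comments optional character vector of provenance comment lines.
#' @return the path, invisibly.
#' @rdname megrank-io
#' @export
write_expression <- function(expr, path, comments = character()) {
  validate_expression(expr)
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_table(df, path, comments)
}

#' Read an expression matrix from TSV
#'
#' @param path TSV file with a `gene_id` column followed by sample columns.
#' @return validated genes x samples numeric matrix.
#' @rdname megrank-io
#' @export
read_expression <- function(path) {
  df <- read_tsv_table(path)
  if (names(df)[1] != "gene_id")
    stop("expression file must start with a `gene_id` column", call. = FALSE)
  for (j in seq_along(df)[-1]) {
    suppressWarnings(num <- as.numeric(df[[j]]))
    if (anyNA(num)) {
      row <- which(is.na(num))[1]
      stop(sprintf("non-numeric expression cell at gene %s, sample %s",
                   df$gene_id[row], names(df)[j]), call. = FALSE)
    }
    df[[j]] <- num
  }
  expr <- as.matrix(df[, -1, drop = FALSE])
  rownames(expr) <- df$gene_id
  validate_expression(expr)
  expr
}

#' Write sample metadata as TSV
#' @param meta metadata data frame (`sample_id`, `patient_id`, `group`,
#'   optionally `timepoint`).
#' @rdname megrank-io
#' @export
write_sample_metadata <- function(meta, path, comments = character()) {
  validate_metadata(meta)
  write_tsv_table(meta, path, comments)
}

#' Read sample metadata from TSV
#' @rdname megrank-io
#' @export
read_sample_metadata <- function(path) {
  meta <- read_tsv_table(path)
  validate_metadata(meta)
  meta
}

#' Read an undirected interaction network from a two-column edge list
#'
#' Self-loops are dropped and duplicated undirected pairs (including
#' reversed duplicates) collapse to a single edge.
#'
#' @param nodes optional character vector of gene identifiers to include as
#'   vertices even when they carry no edge (isolated genes are legitimate
#'   network members but a bare edge list cannot represent them).
#' @rdname megrank-io
#' @export
read_network <- function(path, nodes = NULL) {
  df <- read_tsv_table(path)
  if (!all(c("gene_a", "gene_b") %in% names(df)))
    stop("edge list must have columns `gene_a` and `gene_b`", call. = FALSE)
  df <- df[, c("gene_a", "gene_b")]
  loops <- df$gene_a == df$gene_b
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped from edge list")
    df <- df[!loops, , drop = FALSE]
  }
  key <- paste(pmin(df$gene_a, df$gene_b), pmax(df$gene_a, df$gene_b))
  df <- df[!duplicated(key), , drop = FALSE]
  verts <- union(nodes, unique(c(df$gene_a, df$gene_b)))
  igraph::graph_from_data_frame(df, directed = FALSE,
                                vertices = data.frame(name = verts))
}

#' Write a network as a two-column TSV edge list
#' @param network an undirected igraph graph.
#' @rdname megrank-io
#' @export
write_network <- function(network, path, comments = character()) {
  el <- igraph::as_edgelist(network, names = TRUE)
  df <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                   stringsAsFactors = FALSE)
  write_tsv_table(df, path, comments)
}

#' Write planted simulation truth as TSV (`gene_id`, `role`, `group`)
#' @param truth a [planted_truth()] object.
#' @rdname megrank-io
#' @export
write_truth <- function(truth, path, comments = character()) {
  rows <- list(
    data.frame(gene_id = truth$de_up, role = "de_up", group = NA_character_),
    data.frame(gene_id = truth$de_down, role = "de_down", group = NA_character_))
  for (g in names(truth$monotone_up)) {
    rows <- c(rows, list(
      data.frame(gene_id = truth$monotone_up[[g]], role = "monotone_up", group = g),
      data.frame(gene_id = truth$monotone_down[[g]], role = "monotone_down", group = g)))
  }
  df <- do.call(rbind, rows)
  write_tsv_table(df, path, comments)
}
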