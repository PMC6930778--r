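#' Classify treatment response from direction concordance
#'
#' A monotonically expressed gene whose trend over treatment runs opposite
#' to its disease-vs-control direction is drifting back toward control
#' levels — a "good response" gene. A gene whose trend matches its
#' disease-vs-control direction drifts further away — a "bad response"
#' gene. The rule is an XOR on the two direction tokens: flipping exactly
#' one direction flips the class, flipping both preserves it.
#'
#' @param meg_direction monotone trend direction(s), `"up"` or `"down"`.
#' @param deg_direction differential-expression direction(s) (case vs.
#'   control), `"up"` (overexpressed) or `"down"` (underexpressed).
#' @return `"good"` or `"bad"`, vectorized over the inputs.
#' @export
#' @examples
#' classify_response("up", "down")  # drifts back toward control: good
#' classify_response("up", "up")    # drifts further away: bad
classify_response <- function(meg_direction, deg_direction) {
  check_dir <- function(x, what) {
    bad <- setdiff(unique(x), c("up", "down"))
    if (length(bad))
      stop(sprintf("unknown %s token(s): %s", what, paste(bad, collapse = ", ")),
           call. = FALSE)
  }
  check_dir(meg_direction, "meg_direction")
  check_dir(deg_direction, "deg_direction")
  if (length(meg_direction) != length(deg_direction))
    stop("direction vectors must have equal length", call. = FALSE)
  ifelse(meg_direction != deg_direction, "good", "bad")
}

#' Classify every MEG of a group against the DEG directions
#'
#' Joins monotone directions with cross-sectional differential-expression
#' directions and applies [classify_response()]. Every MEG must be present
#' in the DEG table — the screening pipeline guarantees this by
#' construction, so a missing gene signals a wiring bug and raises an
#' error. Output is sorted good-before-bad, then by gene symbol.
#'
#' @param megs data frame with `gene_id`, `group`, `meg_direction`
#'   (from [find_megs()] or a curated table).
#' @param degs data frame with `gene_id`, `direction`
#'   (from [select_degs()] or a curated table).
#' @return data frame: `gene_id`, `group`, `meg_direction`,
#'   `deg_direction`, `classification`.
#' @export
classify_all <- function(megs, degs) {
  if (!nrow(megs)) {
    return(data.frame(gene_id = character(0), group = character(0),
                      meg_direction = character(0),
                      deg_direction = character(0),
                      classification = character(0),
                      stringsAsFactors = FALSE))
  }
  idx <- match(megs$gene_id, degs$gene_id)
  if (anyNA(idx))
    stop("MEG(s) absent from the DEG set (pipeline wiring bug): ",
         paste(megs$gene_id[is.na(idx)], collapse = ", "), call. = FALSE)
  out <- data.frame(gene_id = megs$gene_id, group = megs$group,
                    meg_direction = megs$meg_direction,
                    deg_direction = degs$direction[idx],
                    stringsAsFactors = FALSE)
  out$classification <- classify_response(out$meg_direction, out$deg_direction)
  out <- out[order(out$classification != "good", out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split patients into responders and nonresponders by first relapse time
#'
#' Patients whose first relapse came later than `responder_min_months`
#' after treatment start are responders; earlier than
#' `nonresponder_max_months`, nonresponders; the intermediate band is
#' excluded from analysis as ambiguous.
#'
#' @param records data frame with `patient_id` and `category`, the category
#'   one of `">60 months"`, `"24-60 months"`, `"<24 months"` (see the
#'   packaged `table1_patients.tsv` fixture).
#' @param responder_min_months,nonresponder_max_months category thresholds;
#'   the defaults (60, 24) match the declared category set.
#' @return list with `responders`, `nonresponders`, `excluded`
#'   (character vectors of patient ids; a partition of the input).
#' @export
#' @examples
#' tab1 <- read_patient_table(system.file("extdata", "table1_patients.tsv",
#'                                        package = "megrank"))
#' lengths(filter_patients(tab1))
filter_patients <- function(records, responder_min_months = 60,
                            nonresponder_max_months = 24) {
  if (!nrow(records)) {
    return(list(responders = character(0), nonresponders = character(0),
                excluded = character(0)))
  }
  declared <- c(sprintf(">%d months", responder_min_months),
                sprintf("%d-%d months", nonresponder_max_months, responder_min_months),
                sprintf("<%d months", nonresponder_max_months))
  unknown <- setdiff(unique(records$category), declared)
  if (length(unknown))
    stop("unknown first-relapse category: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  pid <- as.character(records$patient_id)
  list(responders = pid[records$category == declared[1]],
       nonresponders = pid[records$category == declared[3]],
       excluded = pid[records$category == declared[2]])
}

#' Read a patient first-relapse table (`patient_id`, `category`)
#' @param path TSV file path.
#' @return data frame.
#' @export
read_patient_table <- function(path) {
  df <- read_tsv_table(path)
  req <- c("patient_id", "category")
  if (!all(req %in% names(df)))
    stop("patient table needs columns `patient_id` and `category`", call. = FALSE)
  df
}

#' Read a curated MEG table
#'
#' Expected columns: `gene_id`, `group`, `meg_direction`, `deg_direction`,
#' and optionally `classification` (as in the packaged `table2_megs.tsv`
#' fixture, which carries the published direction pairs).
#' @param path TSV file path.
#' @return data frame.
#' @export
read_meg_table <- function(path) {
  df <- read_tsv_table(path)
  req <- c("gene_id", "group", "meg_direction", "deg_direction")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("MEG table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}
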