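#' Read a GMT gene-set file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicated set names in GMT file")
  sets
}

#' Write gene sets as GMT
#'
#' @param sets Named list of character vectors (or a `gene_set_collection`).
#' @param path Output path.
#' @param descriptions Optional character vector, one per set (defaults to
#'   `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  sets <- .as_sets(sets)
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write an expression matrix as TSV
#'
#' Rows are features; the first column holds the feature id.
#'
#' @param expr Numeric matrix, features x samples.
#' @param path Output path.
#' @param id_column Name of the id column (default `"feature_id"`).
#' @export
write_expression_tsv <- function(expr, path, id_column = "feature_id") {
  .check_expr(expr)
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_expression_tsv()]
#'
#' @param path Input path.
#' @return Numeric matrix with feature rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix in GCT 1.2 format
#'
#' @inheritParams write_expression_tsv
#' @export
write_gct <- function(expr, path) {
  .check_expr(expr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(expr), ncol(expr), sep = "\t")), con)
  header <- paste(c("NAME", "Description", colnames(expr)), collapse = "\t")
  writeLines(header, con)
  body <- apply(expr, 1, function(x) paste(x, collapse = "\t"))
  writeLines(paste(rownames(expr), "na", body, sep = "\t"), con)
  invisible(path)
}

#' Write a survival table as TSV
#'
#' @param surv Data frame with columns `sample`, `time`, `event` and any
#'   covariates.
#' @param path Output path.
#' @export
write_survival_tsv <- function(surv, path) {
  .check_surv(surv)
  utils::write.table(surv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival table written by [write_survival_tsv()]
#' @param path Input path.
#' @return Data frame with columns `sample`, `time`, `event`, covariates.
#' @export
read_survival_tsv <- function(path) {
  surv <- utils::read.delim(path, stringsAsFactors = FALSE)
  surv$sample <- as.character(surv$sample)
  .check_surv(surv)
  surv
}

#' Serialize cohort ground truth as JSON
#'
#' @param truth A `cohort_truth` object from [generate_cohort()].
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "cohort_truth"))
  payload <- list(
    subtype = as.list(truth$subtype),
    modulator_pairs = truth$modulator_pairs,
    prognostic_lnc = as.list(truth$prognostic_lnc),
    purity = as.list(truth$purity),
    seed = truth$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read cohort ground truth written by [write_truth_json()]
#' @param path Input path.
#' @return A `cohort_truth` object.
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- list(
    subtype = unlist(x$subtype),
    modulator_pairs = as.data.frame(x$modulator_pairs,
                                    stringsAsFactors = FALSE),
    prognostic_lnc = unlist(x$prognostic_lnc),
    purity = unlist(x$purity),
    seed = x$seed
  )
  class(truth) <- "cohort_truth"
  truth
}
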