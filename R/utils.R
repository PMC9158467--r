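# Internal helpers shared across modules.

# 31-bit polynomial hash of a character id; used to key per-feature RNG
# streams so results are independent of feature order.
.hash_id <- function(id) {
  h <- 0
  for (ch in utf8ToInt(as.character(id))) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

.key_seed <- function(seed, id) {
  as.integer(((as.numeric(seed) %% 2147483647) * 1009 + .hash_id(id)) %% 2147483647)
}

# Evaluate `expr` under set.seed(seed) without clobbering the caller's RNG
# state.
.with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  expr
}

.check_expr <- function(expr, arg = "expr") {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop(sprintf("`%s` must be a numeric matrix (features x samples)", arg))
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop(sprintf("`%s` must have feature rownames and sample colnames", arg))
  if (anyDuplicated(rownames(expr)))
    stop(sprintf("duplicated feature identifiers in `%s`", arg))
  if (anyDuplicated(colnames(expr)))
    stop(sprintf("duplicated sample identifiers in `%s`", arg))
  if (!all(is.finite(expr)))
    stop(sprintf("non-finite values in `%s`", arg))
  invisible(expr)
}

.check_surv <- function(surv) {
  if (!is.data.frame(surv) || !all(c("sample", "time", "event") %in% names(surv)))
    stop("`surv` must be a data.frame with columns sample, time, event")
  if (anyDuplicated(surv$sample)) stop("duplicated sample ids in `surv`")
  if (any(!is.finite(surv$time)) || any(surv$time <= 0))
    stop("survival times must be positive and finite")
  if (!all(surv$event %in% c(0, 1))) stop("event indicator must be 0/1")
  invisible(surv)
}

# Accepts either a named list of gene sets or a gene_set_collection and
# returns the named list.
.as_sets <- function(sets) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("gene sets must be a named list of character vectors")
  if (any(lengths(sets) == 0)) stop("gene sets must be non-empty")
  sets
}

# z-score matrix rows; constant rows map to 0 rather than NaN
.scale_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  out <- (m - mu) / ifelse(sd > 0, sd, 1)
  out[sd == 0, ] <- 0
  out
}

# Align a named (or positional) per-sample vector against surv$sample.
.align_score <- function(score, surv) {
  if (!is.null(names(score))) {
    missing <- setdiff(surv$sample, names(score))
    if (length(missing))
      stop("score is missing samples: ", paste(utils::head(missing, 5), collapse = ", "))
    score <- score[surv$sample]
  } else if (length(score) != nrow(surv)) {
    stop("unnamed score must have one value per survival row")
  }
  as.numeric(score)
}
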