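#' Single-sample gene-set activity scores
#'
#' Rank-based single-sample enrichment scoring. For each sample, genes are
#' ranked by expression in decreasing order (ties broken by feature id so
#' scoring is reproducible); the score of a set is the sum over ranked
#' positions of the difference between the weighted hit ECDF and the miss
#' ECDF, with hit weights `|rank statistic|^alpha` (the rank statistic of the
#' gene at position i is `N - i + 1`). This is the classical ssGSEA
#' integrated random walk. The `"gsva"` method standardizes each gene across
#' samples before ranking and reports the signed maximum deviation of the
#' walk instead of its integral.
#'
#' @param expr Numeric matrix, genes x samples, log-scale expression.
#' @param sets Named list of gene sets (or a `gene_set_collection`).
#' @param alpha Weighting exponent on the rank statistic (default 0.25).
#' @param normalize If `TRUE`, divide all scores by the range (max - min)
#'   of the whole score matrix.
#' @param min_size Minimum number of set members present in `expr`; smaller
#'   sets are dropped with a warning.
#' @param method `"ssgsea"` (integrated walk) or `"gsva"` (standardize +
#'   max deviation).
#' @return Numeric matrix, sets x samples, with attribute `method`.
#' @export
score_gene_sets <- function(expr, sets, alpha = 0.25, normalize = FALSE,
                            min_size = 5, method = c("ssgsea", "gsva")) {
  method <- match.arg(method)
  .check_expr(expr)
  sets <- .as_sets(sets)
  if (nrow(expr) < 2) stop("`expr` must contain at least 2 genes")

  genes <- rownames(expr)
  n <- length(genes)
  present <- lapply(sets, intersect, y = genes)
  sizes <- lengths(present)
  if (all(sizes == 0))
    stop("no gene set overlaps the expression features; missing sets: ",
         paste(names(sets), collapse = ", "))
  drop_small <- sizes < min_size
  drop_full <- sizes == n
  if (any(drop_full))
    warning("dropping set(s) covering all genes (miss ECDF undefined): ",
            paste(names(sets)[drop_full], collapse = ", "))
  if (any(drop_small & !drop_full))
    warning("dropping set(s) with fewer than ", min_size,
            " members present: ",
            paste(names(sets)[drop_small & !drop_full], collapse = ", "))
  keep <- !(drop_small | drop_full)
  if (!any(keep)) stop("no usable gene set after size filtering")
  present <- present[keep]

  vals <- if (method == "gsva") .scale_rows(expr) else expr
  rank_stat <- n:1
  w_stat <- abs(rank_stat)^alpha

  scores <- matrix(NA_real_, length(present), ncol(expr),
                   dimnames = list(names(present), colnames(expr)))
  set_idx <- lapply(present, match, table = genes)
  for (s in seq_len(ncol(vals))) {
    ord <- order(-vals[, s], genes)      # descending, id tie-break
    pos_of_gene <- integer(n)
    pos_of_gene[ord] <- seq_len(n)
    for (k in seq_along(set_idx)) {
      pos <- sort(pos_of_gene[set_idx[[k]]])
      m <- length(pos)
      w <- w_stat[pos]
      if (method == "ssgsea") {
        # sum_i P_hit(i) - sum_i P_miss(i), each ECDF summed in closed form
        hit <- sum(w * (n - pos + 1)) / sum(w)
        miss <- (n * (n + 1) / 2 - sum(n - pos + 1)) / (n - m)
        scores[k, s] <- hit - miss
      } else {
        scores[k, s] <- .es_stat(pos, w, n)
      }
    }
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  attr(scores, "method") <- method
  scores
}

# Signed maximum deviation of the weighted KS walk, evaluated only at the
# positions adjacent to hits (the walk is linear between hits). `pos` are
# sorted hit positions, `w` their (non-negative) weights, `n` the list
# length. Ties between the positive and negative extreme resolve positive.
.es_stat <- function(pos, w, n) {
  m <- length(pos)
  if (m == 0 || m == n) stop("enrichment walk needs both hits and misses")
  sw <- sum(w)
  cw <- if (sw > 0) cumsum(w) / sw else seq_len(m) / m
  mrate <- 1 / (n - m)
  miss_before <- (pos - seq_len(m)) * mrate
  top <- cw - miss_before
  bottom <- c(0, cw[-m]) - miss_before
  hi <- max(top)
  lo <- min(bottom, 0)
  if (hi >= -lo) hi else lo
}

#' Differential gene-set activity between two sample groups
#'
#' Moderated two-sample t test per set (empirical-Bayes variance shrinkage
#' via limma), two-sided p and Benjamini-Hochberg FDR across sets.
#'
#' @param activity Sets x samples score matrix.
#' @param group_a,group_b Disjoint character vectors of sample ids, each of
#'   size >= 3.
#' @return Data frame: `set_name`, `delta` (mean A - mean B), `t_stat`,
#'   `p`, `fdr`, ordered as the input rows.
#' @export
differential_activity <- function(activity, group_a, group_b) {
  tab <- .moderated_two_group(activity, group_a, group_b)
  data.frame(set_name = rownames(activity), delta = tab$delta,
             t_stat = tab$t_stat, p = tab$p, fdr = tab$fdr,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Shared moderated-t engine (limma) for activity rows, lncRNAs and marker
# ranking. delta = mean(group_a) - mean(group_b).
.moderated_two_group <- function(mat, group_a, group_b) {
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  if (length(group_a) < 3 || length(group_b) < 3)
    stop("each group needs at least 3 samples")
  missing <- setdiff(c(group_a, group_b), colnames(mat))
  if (length(missing))
    stop("samples absent from matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  sub <- mat[, c(group_a, group_b), drop = FALSE]
  is_a <- as.numeric(colnames(sub) %in% group_a)
  design <- cbind(Intercept = 1, A = is_a)
  fit <- limma::eBayes(limma::lmFit(sub, design))
  p <- fit$p.value[, "A"]
  t_stat <- fit$t[, "A"]
  # zero-variance rows: no evidence, report t = 0, p = 1
  degenerate <- !is.finite(t_stat)
  t_stat[degenerate] <- 0
  p[degenerate] <- 1
  data.frame(delta = fit$coefficients[, "A"], t_stat = t_stat, p = p,
             fdr = stats::p.adjust(p, "BH"), row.names = rownames(sub))
}

#' Optimal survival cutoff for a continuous score
#'
#' Scans candidate cutoffs at the observed score values, keeping splits in
#' which both strata contain at least `min_prop` of the samples and at least
#' one event, and returns the cutoff maximizing the log-rank statistic. The
#' reported p-value is the naive chi-square p of the chosen split and is not
#' corrected for the maximal selection (a message notes this).
#'
#' @param score Per-sample numeric vector (named by sample id or aligned
#'   with `surv` rows).
#' @param surv Survival data frame (`sample`, `time`, `event`).
#' @param min_prop Minimum fraction of samples per stratum.
#' @return List: `cutoff`, `logrank_chi2`, `p`, `n_high`, `n_low`.
#' @export
km_optimal_cutoff <- function(score, surv, min_prop = 0.1) {
  .check_surv(surv)
  score <- .align_score(score, surv)
  n <- nrow(surv)
  if (n < 10) stop("need at least 10 samples")
  if (sum(surv$event) == 0) stop("log-rank undefined: no events observed")
  cand <- sort(unique(score))
  cand <- cand[-length(cand)]             # score > max splits nothing off
  min_n <- max(1L, ceiling(min_prop * n))
  best <- NULL
  for (cut in cand) {
    high <- score > cut
    if (sum(high) < min_n || sum(!high) < min_n) next
    if (sum(surv$event[high]) < 1 || sum(surv$event[!high]) < 1) next
    sd <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ high)
    if (is.null(best) || sd$chisq > best$logrank_chi2)
      best <- list(cutoff = cut, logrank_chi2 = sd$chisq,
                   p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
                   n_high = sum(high), n_low = sum(!high))
  }
  if (is.null(best)) stop("no admissible cutoff")
  message("km_optimal_cutoff: p-value is uncorrected for cutoff selection")
  best
}
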