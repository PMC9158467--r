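#' Harrell's concordance index
#'
#' Fraction of concordant pairs among comparable pairs: a pair is
#' comparable when the shorter observed time is an event and the times
#' differ; it is concordant when the subject with the shorter time has the
#' higher score, and score ties count 0.5.
#'
#' @param score Per-sample numeric risk score (named or aligned with
#'   `surv`).
#' @param surv Survival data frame.
#' @return Concordance in `[0, 1]`.
#' @export
harrell_cindex <- function(score, surv) {
  .check_surv(surv)
  score <- .align_score(score, surv)
  time <- surv$time
  event <- surv$event
  num <- 0
  den <- 0
  for (i in which(event == 1)) {
    later <- time > time[i]
    den <- den + sum(later)
    num <- num + sum(score[i] > score[later]) +
      0.5 * sum(score[i] == score[later])
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

#' IPCW time-dependent AUC
#'
#' Cumulative/dynamic AUC at each horizon t: cases are subjects with an
#' event by t, controls are subjects observed beyond t, and both sides are
#' weighted by the inverse probability of censoring from the Kaplan-Meier
#' estimator of the censoring distribution (cases at the left limit
#' `G(T-)`, controls at `G(t)`). With no censoring this reduces exactly to
#' the Mann-Whitney rank AUC between cases and controls.
#'
#' @param score Per-sample numeric risk score.
#' @param surv Survival data frame.
#' @param horizons Numeric vector of evaluation times within follow-up.
#' @return Data frame: `horizon`, `auc`, `n_cases`, `n_controls`.
#' @export
time_dependent_auc <- function(score, surv, horizons) {
  .check_surv(surv)
  score <- .align_score(score, surv)
  time <- surv$time
  event <- surv$event
  if (any(horizons > max(time)))
    stop("horizon beyond last observed time")

  cfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- function(t, left = FALSE) {
    # KM of the censoring distribution evaluated at t (or just before t)
    tt <- if (left) cfit$time < t else cfit$time <= t
    if (!any(tt)) return(1)
    cfit$surv[max(which(tt))]
  }

  out <- lapply(horizons, function(t) {
    cases <- which(time <= t & event == 1)
    controls <- which(time > t)
    if (!length(cases) || !length(controls))
      stop("horizon ", t, " lacks cases or controls")
    w_case <- vapply(time[cases], function(ti) {
      g <- G(ti, left = TRUE)
      if (g <= 0) stop("zero censoring-survival weight at horizon ", t)
      1 / g
    }, numeric(1))
    g_t <- G(t)
    if (g_t <= 0) stop("zero censoring-survival weight at horizon ", t)
    w_ctrl <- rep(1 / g_t, length(controls))
    sc <- score[cases]
    st <- score[controls]
    cmp <- outer(sc, st, ">") + 0.5 * outer(sc, st, "==")
    auc <- sum((w_case %o% w_ctrl) * cmp) / (sum(w_case) * sum(w_ctrl))
    data.frame(horizon = t, auc = auc, n_cases = length(cases),
               n_controls = length(controls))
  })
  do.call(rbind, out)
}

#' Compare two concordance indices by paired bootstrap
#'
#' Computes `delta = C_a - C_b` on the full data and a two-sided p-value
#' from the percentile bootstrap distribution of delta over paired sample
#' resamples.
#'
#' @param score_a,score_b Risk scores on identical samples.
#' @param surv Survival data frame.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return List: `delta`, `p`, `c_a`, `c_b`.
#' @export
compare_cindices <- function(score_a, score_b, surv, n_boot = 1000,
                             seed = 1) {
  .check_surv(surv)
  a <- .align_score(score_a, surv)
  b <- .align_score(score_b, surv)
  n <- nrow(surv)
  if (n < 50) warning("fewer than 50 samples: comparison is unstable")
  c_a <- harrell_cindex(a, surv)
  c_b <- harrell_cindex(b, surv)
  deltas <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      sv <- data.frame(sample = sprintf("b%d", seq_len(n)),
                       time = surv$time[idx], event = surv$event[idx])
      if (sum(sv$event) == 0) return(NA_real_)
      tryCatch(harrell_cindex(a[idx], sv) - harrell_cindex(b[idx], sv),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  deltas <- deltas[is.finite(deltas)]
  if (!length(deltas)) stop("no usable bootstrap resamples")
  p_lo <- mean(deltas <= 0)
  p_hi <- mean(deltas >= 0)
  list(delta = c_a - c_b, p = min(1, 2 * min(p_lo, p_hi)), c_a = c_a,
       c_b = c_b)
}

#' Correlate features with a risk score
#'
#' Per-feature correlation (Spearman by default) with BH FDR; features are
#' flagged when `|r| > r_min` and `FDR < fdr_max`. Applies equally to gene
#' expression rows, immune-cell activity rows or checkpoint genes.
#'
#' @param features Features x samples numeric matrix.
#' @param score Per-sample numeric score (named or aligned with columns).
#' @param r_min Absolute correlation threshold (default 0.4).
#' @param fdr_max FDR threshold (default 0.001).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Data frame: `feature`, `r`, `p`, `fdr`, `flagged`; constant
#'   features are skipped with a warning.
#' @export
correlate_with_score <- function(features, score, r_min = 0.4,
                                 fdr_max = 0.001,
                                 method = c("spearman", "pearson")) {
  method <- match.arg(method)
  .check_expr(features, "features")
  if (!is.null(names(score))) {
    shared <- intersect(colnames(features), names(score))
    if (length(shared) < 10) stop("fewer than 10 shared samples")
    features <- features[, shared, drop = FALSE]
    score <- score[shared]
  } else if (length(score) != ncol(features)) {
    stop("unnamed score must have one value per sample column")
  }
  n <- length(score)
  if (n < 10) stop("fewer than 10 shared samples")
  sds <- apply(features, 1, stats::sd)
  if (any(sds == 0))
    warning("skipping constant feature(s): ",
            paste(utils::head(rownames(features)[sds == 0], 5), collapse = ", "))
  keep <- sds > 0
  r <- as.numeric(stats::cor(t(features[keep, , drop = FALSE]), score,
                             method = method))
  # t approximation, standard for both flavors at these sample sizes
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  fdr <- stats::p.adjust(p, "BH")
  data.frame(feature = rownames(features)[keep], r = r, p = p, fdr = fdr,
             flagged = abs(r) > r_min & fdr < fdr_max,
             stringsAsFactors = FALSE, row.names = NULL)
}
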