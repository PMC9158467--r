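#' Intersect subtype-differential lncRNAs with ProLnc modulators
#'
#' Proliferation-associated lncRNAs (PALs) are the intersection of the two
#' evidence streams (union available via `mode = "union"`). Output is
#' sorted by id.
#'
#' @param delncs Character vector of differential lncRNA ids.
#' @param modulators Character vector of modulator lncRNA ids.
#' @param mode `"intersect"` (default) or `"union"`.
#' @return Sorted character vector of PAL ids.
#' @export
intersect_pals <- function(delncs, modulators, mode = c("intersect", "union")) {
  mode <- match.arg(mode)
  out <- if (mode == "intersect") intersect(delncs, modulators) else
    union(delncs, modulators)
  if (!length(out)) warning("empty PAL set")
  sort(unique(out))
}

#' Univariate Cox regression for one feature
#'
#' Single-covariate Cox partial-likelihood fit (Breslow tie handling) with
#' Wald z and p. Fits with `|beta| > 20` are flagged non-converged
#' (monotone-likelihood divergence).
#'
#' @param x Per-sample numeric vector (named by sample id or aligned with
#'   `surv` rows).
#' @param surv Survival data frame (`sample`, `time`, `event`).
#' @param feature Optional feature id stored in the output.
#' @return One-row data frame: `feature`, `beta`, `hr`, `se`, `z`, `p`,
#'   `n`, `events`, `converged`.
#' @export
univariate_cox <- function(x, surv, feature = NA_character_) {
  .check_surv(surv)
  x <- .align_score(x, surv)
  if (sum(surv$event) < 2) stop("need at least 2 events")
  if (stats::sd(x) == 0) stop("constant covariate")
  fit <- survival::coxph(survival::Surv(surv$time, surv$event) ~ x,
                         ties = "breslow")
  s <- summary(fit)
  beta <- unname(stats::coef(fit))
  data.frame(feature = feature, beta = beta, hr = exp(beta),
             se = s$coefficients[1, "se(coef)"],
             z = s$coefficients[1, "z"], p = s$coefficients[1, "Pr(>|z|)"],
             n = length(x), events = sum(surv$event),
             converged = abs(beta) <= 20, stringsAsFactors = FALSE)
}

# univariate Cox over all rows of an expression matrix
.cox_screen <- function(expr, surv) {
  do.call(rbind, lapply(rownames(expr), function(id) {
    univariate_cox(expr[id, ], surv, feature = id)
  }))
}

#' Bootstrap stability selection of prognostic features
#'
#' Two-stage selection mirroring a screen-then-resample design: stage 1
#' keeps features whose full-data univariate Cox p is below `screen_p`;
#' stage 2 draws `runs` subsamples of `ceiling(frac * n)` samples without
#' replacement (per-feature RNG streams keyed by feature id, so the result
#' is independent of feature order) and records the fraction of runs in
#' which the feature reaches `p < alpha`. A feature is selected when its
#' inclusion rate is at least `keep_rate`. Resamples with fewer than 2
#' events are redrawn up to 10 times, then counted as non-significant.
#'
#' @param expr Features x samples expression matrix.
#' @param surv Survival data frame.
#' @param screen_p Stage-1 screening p threshold (default 0.01).
#' @param frac Subsample fraction (default 0.7).
#' @param runs Number of resampling runs (default 1000).
#' @param alpha Per-run significance level (default 0.05).
#' @param keep_rate Minimum inclusion rate (default 0.8).
#' @param seed Integer seed.
#' @param replace Draw resamples with replacement (classical bootstrap)
#'   instead of the default 70% subsampling.
#' @return Data frame: `feature`, `screen_p`, `inclusion_rate`, `selected`.
#'   Features failing stage 1 have `inclusion_rate = NA`.
#' @export
bootstrap_stability_select <- function(expr, surv, screen_p = 0.01,
                                       frac = 0.7, runs = 1000,
                                       alpha = 0.05, keep_rate = 0.8,
                                       seed = 1, replace = FALSE) {
  .check_expr(expr)
  .check_surv(surv)
  n <- nrow(surv)
  if (n < 30) stop("need at least 30 samples")
  if (sum(surv$event) < 10) stop("need at least 10 events")
  screen <- .cox_screen(expr, surv)
  m <- ceiling(frac * n)

  rate <- vapply(seq_len(nrow(screen)), function(i) {
    if (screen$p[i] >= screen_p) return(NA_real_)
    id <- screen$feature[i]
    x <- .align_score(expr[id, ], surv)
    .with_seed(.key_seed(seed, id), {
      hits <- 0L
      short <- 0L
      for (r in seq_len(runs)) {
        idx <- sample.int(n, m, replace = replace)
        tries <- 0L
        while (sum(surv$event[idx]) < 2 && tries < 10) {
          idx <- sample.int(n, m, replace = replace)
          tries <- tries + 1L
        }
        if (sum(surv$event[idx]) < 2 || stats::sd(x[idx]) == 0) {
          short <- short + 1L
          next
        }
        fit <- survival::coxph(
          survival::Surv(surv$time[idx], surv$event[idx]) ~ x[idx],
          ties = "breslow")
        pr <- summary(fit)$coefficients[1, "Pr(>|z|)"]
        if (is.finite(pr) && pr < alpha) hits <- hits + 1L
      }
      if (short > 0)
        message(id, ": ", short, " resample(s) lacked events, counted ",
                "non-significant")
      hits / runs
    })
  }, numeric(1))

  data.frame(feature = screen$feature, screen_p = screen$p,
             inclusion_rate = rate,
             selected = !is.na(rate) & rate >= keep_rate,
             stringsAsFactors = FALSE)
}

#' Cross-cohort consensus of prognostic effects
#'
#' A feature is kept when it is significant (`p < alpha`) in at least
#' `min_cohorts` cohorts and every significant cohort agrees on the sign of
#' its log-hazard; features significant with opposite signs are excluded.
#' Features absent from a cohort count as non-significant there.
#'
#' @param cox_tables Named list of per-cohort data frames as produced by
#'   [univariate_cox()] (columns `feature`, `beta`, `p`).
#' @param min_cohorts Minimum number of significant cohorts (default 3).
#' @param alpha Per-cohort significance level (default 0.05).
#' @return Data frame: `feature`, `n_significant`, `sign_consistent`,
#'   `selected`, `direction` (`"risk"`, `"protective"` or `NA`).
#' @export
cross_cohort_consensus <- function(cox_tables, min_cohorts = 3,
                                   alpha = 0.05) {
  if (!is.list(cox_tables) || length(cox_tables) < 2)
    stop("need at least 2 cohort tables")
  feats <- sort(unique(unlist(lapply(cox_tables, `[[`, "feature"))))
  res <- lapply(feats, function(f) {
    sig_beta <- numeric(0)
    for (tab in cox_tables) {
      j <- match(f, tab$feature)
      if (is.na(j)) next
      if (is.finite(tab$p[j]) && tab$p[j] < alpha)
        sig_beta <- c(sig_beta, tab$beta[j])
    }
    consistent <- length(sig_beta) == 0 ||
      all(sign(sig_beta) == sign(sig_beta[1]))
    sel <- length(sig_beta) >= min_cohorts && consistent
    data.frame(feature = f, n_significant = length(sig_beta),
               sign_consistent = consistent, selected = sel,
               direction = if (sel) {
                 if (sig_beta[1] > 0) "risk" else "protective"
               } else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
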