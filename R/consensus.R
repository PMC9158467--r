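#' Consensus k-means clustering over subsampled samples
#'
#' For each k in `k_range`, repeatedly subsamples a fraction of the samples,
#' runs k-means (Euclidean, k-means++ initialization from the iteration's
#' RNG stream) and accumulates the consensus matrix
#' `consensus(i, j) = co-cluster count / co-subsample count`. Final
#' assignments come from average-linkage hierarchical clustering of
#' `1 - consensus` cut at k. Activity rows are z-scored first so every
#' pathway contributes equally to the Euclidean metric.
#'
#' @param activity Sets x samples activity matrix.
#' @param k_range Integer vector of cluster numbers (default `2:9`).
#' @param n_iter Subsampling iterations per k (default 1000).
#' @param sample_frac Fraction of samples drawn (without replacement) per
#'   iteration.
#' @param seed Integer seed.
#' @return List of `consensus_result` objects, one per k, each with fields
#'   `k`, `consensus_matrix`, `assignments` (named integer), `pac`,
#'   `mean_silhouette`.
#' @export
consensus_cluster <- function(activity, k_range = 2:9, n_iter = 1000,
                              sample_frac = 0.8, seed = 1) {
  .check_expr(activity, "activity")
  n <- ncol(activity)
  if (n < 2 * max(k_range)) stop("need at least 2 * max(k_range) samples")
  if (sample_frac <= 0 || sample_frac > 1)
    stop("sample_frac must be in (0, 1]")
  x <- t(.scale_rows(activity))           # samples x features
  d_full <- stats::dist(x)
  ids <- colnames(activity)
  set.seed(seed)

  lapply(k_range, function(k) {
    co_cluster <- matrix(0, n, n)
    co_sample <- matrix(0, n, n)
    m <- max(k, round(sample_frac * n))
    for (it in seq_len(n_iter)) {
      idx <- sort(sample.int(n, m))
      cl <- .kmeanspp(x[idx, , drop = FALSE], k)
      same <- outer(cl, cl, "==")
      co_cluster[idx, idx] <- co_cluster[idx, idx] + same
      co_sample[idx, idx] <- co_sample[idx, idx] + 1
    }
    cm <- ifelse(co_sample > 0, co_cluster / pmax(co_sample, 1), 0)
    never <- co_sample == 0
    diag(never) <- FALSE
    if (any(never))
      warning(sum(never) / 2, " sample pair(s) never co-subsampled; ",
              "their consensus entries are 0")
    diag(cm) <- 1
    dimnames(cm) <- list(ids, ids)
    hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
    assign <- stats::cutree(hc, k)
    names(assign) <- ids
    sil <- cluster::silhouette(assign, d_full)
    res <- list(k = k, consensus_matrix = cm, assignments = assign,
                pac = pac_score(cm),
                mean_silhouette = mean(sil[, "sil_width"]))
    class(res) <- "consensus_result"
    res
  })
}

# k-means++ seeding followed by Lloyd iterations via stats::kmeans.
.kmeanspp <- function(x, k) {
  n <- nrow(x)
  if (k >= n) return(seq_len(n))
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      # fewer distinct points than k: pad with distinct rows
      pick <- which(!duplicated(x))[j + 1]
      if (is.na(pick)) pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2)
    }
    centers[j + 1, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j + 1, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers <- centers[!duplicated(centers), , drop = FALSE]
  stats::kmeans(x, centers, iter.max = 25)$cluster
}

#' Proportion of ambiguous clustering
#'
#' Fraction of strictly-upper-triangle consensus entries strictly between
#' `lower` and `upper`; lower PAC indicates cleaner clustering.
#'
#' @param consensus_matrix Symmetric samples x samples matrix in `[0, 1]`.
#' @param lower,upper Ambiguity band limits (default 0.1 and 0.9).
#' @return PAC in `[0, 1]`.
#' @export
pac_score <- function(consensus_matrix, lower = 0.1, upper = 0.9) {
  if (lower >= upper) stop("`lower` must be < `upper`")
  if (!is.matrix(consensus_matrix) ||
      nrow(consensus_matrix) != ncol(consensus_matrix))
    stop("consensus_matrix must be square")
  if (any(consensus_matrix < 0 | consensus_matrix > 1))
    stop("consensus entries must lie in [0, 1]")
  up <- consensus_matrix[upper.tri(consensus_matrix)]
  mean(up > lower & up < upper)
}

#' Silhouette-based core sample filter
#'
#' Computes Euclidean silhouette widths of the samples under the given
#' assignments (on row-z-scored activity) and removes peripheral samples
#' with width <= 0. Samples in singleton clusters get width 0 and are
#' removed with a warning.
#'
#' @param activity Sets x samples activity matrix.
#' @param assignments Named cluster vector (sample -> cluster).
#' @return List: `core` (character vector of retained samples), `widths`
#'   (named numeric silhouette widths).
#' @export
silhouette_core_filter <- function(activity, assignments) {
  .check_expr(activity, "activity")
  assignments <- assignments[colnames(activity)]
  if (anyNA(assignments)) stop("assignments must cover all samples")
  cl <- as.integer(factor(assignments))
  if (length(unique(cl)) < 2)
    stop("silhouette undefined for a single cluster")
  if (any(table(cl) == 1))
    warning("singleton cluster(s): their samples get width 0 and are removed")
  d <- stats::dist(t(.scale_rows(activity)))
  sil <- cluster::silhouette(cl, d)
  widths <- sil[, "sil_width"]
  names(widths) <- colnames(activity)
  list(core = names(widths)[widths > 0], widths = widths)
}

#' Subtype-differential lncRNAs
#'
#' Moderated t per lncRNA between the two assignment groups (restricted to
#' the provided samples, e.g. the silhouette core), BH FDR, and a DElnc
#' flag at `|difference| >= lfc_min` and `FDR < fdr_max`.
#'
#' @param lnc_expr lncRNA x samples log2 expression matrix.
#' @param assignments Named two-level vector (sample -> subtype).
#' @param lfc_min Minimum absolute mean log2 difference (default 1).
#' @param fdr_max FDR threshold (default 0.05).
#' @return Data frame: `lnc_id`, `delta`, `t_stat`, `p`, `fdr`, `de`.
#' @export
differential_lncrnas <- function(lnc_expr, assignments, lfc_min = 1,
                                 fdr_max = 0.05) {
  .check_expr(lnc_expr, "lnc_expr")
  assignments <- assignments[names(assignments) %in% colnames(lnc_expr)]
  lev <- sort(unique(as.character(assignments)))
  if (length(lev) != 2) stop("assignments must contain exactly two groups")
  ga <- names(assignments)[assignments == lev[1]]
  gb <- names(assignments)[assignments == lev[2]]
  if (length(ga) == 0 || length(gb) == 0) stop("empty group")
  tab <- .moderated_two_group(lnc_expr, ga, gb)
  data.frame(lnc_id = rownames(lnc_expr), delta = tab$delta,
             t_stat = tab$t_stat, p = tab$p, fdr = tab$fdr,
             de = abs(tab$delta) >= lfc_min & tab$fdr < fdr_max,
             stringsAsFactors = FALSE, row.names = NULL)
}
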