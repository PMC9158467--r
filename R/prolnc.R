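#' Purity-adjusted partial correlation of a lncRNA and an mRNA
#'
#' First-order partial Pearson correlation of `lnc_vec` and `mrna_vec` given
#' the confounder `purity_vec`:
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`,
#' with `t = pcc * sqrt(dof / (1 - pcc^2))`, `dof = n - 3`, and a two-sided
#' p from the t distribution.
#'
#' @param lnc_vec,mrna_vec,purity_vec Numeric vectors of equal length
#'   `n >= 5`, none constant.
#' @return List: `pcc`, `dof`, `t_stat`, `p`.
#' @export
purity_adjusted_association <- function(lnc_vec, mrna_vec, purity_vec) {
  n <- length(lnc_vec)
  if (length(mrna_vec) != n || length(purity_vec) != n)
    stop("input vectors must have equal length")
  if (n < 5) stop("need at least 5 samples")
  for (v in list(lnc_vec, mrna_vec, purity_vec))
    if (stats::sd(v) == 0) stop("constant input vector")
  r_xy <- stats::cor(mrna_vec, lnc_vec)
  r_xz <- stats::cor(mrna_vec, purity_vec)
  r_yz <- stats::cor(lnc_vec, purity_vec)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12)
    stop("a variable is perfectly correlated with purity")
  pcc <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  pcc <- max(-1, min(1, pcc))
  dof <- n - 3
  t_stat <- if (abs(pcc) < 1) pcc * sqrt(dof / (1 - pcc^2)) else
    sign(pcc) * Inf
  p <- 2 * stats::pt(-abs(t_stat), df = dof)
  list(pcc = pcc, dof = dof, t_stat = t_stat, p = p)
}

#' Rank the transcriptome for one lncRNA by ordered index
#'
#' Computes the purity-adjusted partial correlation of the lncRNA with every
#' mRNA, converts it to the ordered index `OI = sign(pcc) * (-log10 p)` and
#' sorts mRNAs by OI descending (ties broken by id). Numerical p = 0 is
#' capped at `OI = sign(pcc) * 320` with a warning; constant mRNA rows get
#' `pcc = 0, p = 1` with a warning.
#'
#' @param lnc_id Row of `lnc_expr` to rank against.
#' @param mrna_expr mRNA x samples matrix.
#' @param lnc_expr lncRNA x samples matrix.
#' @param purity Named per-sample purity vector.
#' @return Data frame (class `ranked_list`): `mrna_id`, `pcc`, `p`, `oi`,
#'   ordered by OI descending; attribute `lnc_id`.
#' @export
build_rank_list <- function(lnc_id, mrna_expr, lnc_expr, purity) {
  .check_expr(mrna_expr, "mrna_expr")
  if (!lnc_id %in% rownames(lnc_expr)) stop("unknown lncRNA id: ", lnc_id)
  samples <- intersect(colnames(mrna_expr),
                       intersect(colnames(lnc_expr), names(purity)))
  if (length(samples) < 5) stop("fewer than 5 shared samples")
  .rank_list_fast(lnc_id, lnc_expr[lnc_id, samples],
                  mrna_expr[, samples, drop = FALSE], purity[samples])
}

# vectorized partial correlation + OI for one lncRNA vector
.rank_list_fast <- function(lnc_id, y, mrna, z) {
  n <- length(y)
  r_xy <- suppressWarnings(as.numeric(stats::cor(t(mrna), y)))
  r_xz <- suppressWarnings(as.numeric(stats::cor(t(mrna), z)))
  r_yz <- stats::cor(y, z)
  if (abs(r_yz) >= 1) stop("lncRNA perfectly correlated with purity")
  pcc <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  bad <- !is.finite(pcc)
  if (any(bad)) {
    warning(sum(bad), " degenerate mRNA row(s): pcc set to 0")
    pcc[bad] <- 0
  }
  pcc <- pmax(-1, pmin(1, pcc))
  dof <- n - 3
  t_stat <- ifelse(abs(pcc) < 1, pcc * sqrt(dof / pmax(1 - pcc^2, 1e-300)),
                   sign(pcc) * Inf)
  p <- 2 * stats::pt(-abs(t_stat), df = dof)
  oi <- sign(pcc) * (-log10(p))
  if (any(p == 0)) {
    warning("numerical p = 0: OI capped at +/-320")
    oi[p == 0] <- sign(pcc[p == 0]) * 320
  }
  ids <- rownames(mrna)
  ord <- order(-oi, ids)
  out <- data.frame(mrna_id = ids[ord], pcc = pcc[ord], p = p[ord],
                    oi = oi[ord], stringsAsFactors = FALSE)
  attr(out, "lnc_id") <- lnc_id
  class(out) <- c("ranked_list", class(out))
  out
}

#' Preranked gene-set enrichment on an OI-ranked list
#'
#' Weighted Kolmogorov-Smirnov walk down the ranked list: hits increment by
#' `|OI|^weight` (normalized over hits), misses decrement by `1/(N - Nh)`;
#' the enrichment score is the signed maximum deviation. The null
#' distribution comes from `n_perm` random same-size gene sets drawn from
#' the ranked ids; NES is the ES divided by the mean |null ES| of matching
#' sign and the permutation p uses the add-one rule within the
#' matching-sign null pool.
#'
#' @param ranked A `ranked_list` from [build_rank_list()], or a named
#'   numeric OI vector sorted descending.
#' @param pathway Character vector of gene ids (>= 5 must be present).
#' @param weight Exponent on |OI| (default 1).
#' @param n_perm Number of random sets (default 1000).
#' @param seed Integer seed.
#' @param min_size Minimum pathway genes present (default 5; set lower only
#'   for didactic walks on tiny lists).
#' @return List: `es`, `nes`, `p_perm`, `n_hits`.
#' @export
preranked_gsea <- function(ranked, pathway, weight = 1, n_perm = 1000,
                           seed = 1, min_size = 5) {
  if (is.data.frame(ranked)) {
    oi <- ranked$oi
    ids <- ranked$mrna_id
  } else {
    oi <- as.numeric(ranked)
    ids <- names(ranked)
  }
  if (is.unsorted(rev(oi))) stop("ranked list must be sorted by OI descending")
  n <- length(oi)
  pos <- sort(match(intersect(pathway, ids), ids))
  m <- length(pos)
  if (m == 0) stop("pathway has no genes in the ranked list")
  if (m == n) stop("pathway covers the whole list: no misses")
  if (m < min_size)
    stop("fewer than ", min_size, " pathway genes present in the ranked list")
  w_all <- abs(oi)^weight
  es <- .es_stat(pos, w_all[pos], n)
  null_es <- .with_seed(seed, .null_es(w_all, m, n, n_perm))
  c(.nes_p(es, null_es, n_perm), list(es = es, n_hits = m))
}

.null_es <- function(w_all, m, n, n_perm) {
  vapply(seq_len(n_perm), function(b) {
    pos <- sort(sample.int(n, m))
    .es_stat(pos, w_all[pos], n)
  }, numeric(1))
}

# NES + sign-matched add-one permutation p for an observed ES
.nes_p <- function(es, null_es, n_perm) {
  same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  p <- if (length(same))
    (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  else 1 / (n_perm + 1)
  list(nes = nes, p_perm = p)
}

#' Final significance index
#'
#' `FSI = (1 - 2 * FDR) * sign(ES)`, mapping enrichment confidence to
#' `[-1, 1]` with the sign carrying the direction (`sign(0) = 0`).
#'
#' @param fdr FDR in `[0, 1]` (vectorized).
#' @param es Enrichment score (vectorized).
#' @return Numeric FSI values.
#' @export
final_significance_index <- function(fdr, es) {
  if (any(fdr < 0 | fdr > 1)) stop("fdr must lie in [0, 1]")
  (1 - 2 * fdr) * sign(es)
}

#' ProLnc: score every lncRNA against each pathway
#'
#' For every lncRNA, builds the purity-adjusted OI-ranked mRNA list, runs
#' the preranked enrichment walk against each pathway with a permutation
#' null (one RNG stream per lncRNA keyed by its id, so results do not
#' depend on lncRNA order), and converts enrichment
#' confidence into the final significance index. The default FDR is the
#' GSEA-native pooled-null NES estimate computed within each lncRNA's
#' enrichment run (Subramanian-style: the tail fraction of the lncRNA's
#' pooled normalized null scores relative to its observed tail fraction),
#' which can reach 0 for unambiguous modulators; `fdr_method = "bh"` uses
#' Benjamini-Hochberg on the permutation p-values across all pairs instead
#' (note that BH of add-one permutation p-values is floored at
#' `~1/(n_perm + 1)` and cannot reach very small thresholds).
#'
#' The default null (`null_method = "sample"`) permutes the lncRNA's
#' sample labels and reruns the whole association-ranking-enrichment chain,
#' which preserves the inter-gene correlation of pathway modules; random
#' same-size gene sets (`null_method = "geneset"`) are faster but
#' anti-conservative when pathway genes are co-expressed modules, as they
#' are in tumor transcriptomes.
#'
#' @param lnc_expr lncRNA x samples log2 expression matrix.
#' @param mrna_expr mRNA x samples log2 expression matrix.
#' @param purity Named per-sample purity vector.
#' @param pathways Named list of gene sets (or a `gene_set_collection`).
#' @param fdr_max Modulator flag threshold on the FDR (default 0.001; this
#'   forces `|FSI| > 1 - 2 * fdr_max`).
#' @param weight Exponent on |OI| in the enrichment walk.
#' @param n_perm Permutations per (lncRNA, pathway-size) pair.
#' @param seed Integer seed.
#' @param fdr_method `"pooled"` (default) or `"bh"`.
#' @param null_method `"sample"` (default; permute the lncRNA across
#'   samples and rerun the association-ranking-enrichment chain) or
#'   `"geneset"` (random same-size gene sets, shared across pathways of
#'   equal size).
#' @param min_size Minimum pathway genes present (smaller pathways are
#'   skipped with a warning).
#' @return Data frame, one row per (lncRNA, pathway): `lnc_id`, `pathway`,
#'   `n_hits`, `es`, `nes`, `p_perm`, `fdr`, `fsi`, `flagged`.
#' @export
run_prolnc <- function(lnc_expr, mrna_expr, purity, pathways,
                       fdr_max = 0.001, weight = 1, n_perm = 1000, seed = 1,
                       fdr_method = c("pooled", "bh"),
                       null_method = c("sample", "geneset"), min_size = 5) {
  fdr_method <- match.arg(fdr_method)
  null_method <- match.arg(null_method)
  .check_expr(lnc_expr, "lnc_expr")
  .check_expr(mrna_expr, "mrna_expr")
  pathways <- .as_sets(pathways)
  samples <- intersect(colnames(mrna_expr),
                       intersect(colnames(lnc_expr), names(purity)))
  if (length(samples) < 5) stop("fewer than 5 shared samples")
  mrna <- mrna_expr[, samples, drop = FALSE]
  z <- purity[samples]
  lncs <- rownames(lnc_expr)
  n <- nrow(mrna)
  ns <- length(samples)

  present <- lapply(pathways, intersect, y = rownames(mrna))
  sizes <- lengths(present)
  if (any(sizes < min_size)) {
    warning("skipping pathway(s) with fewer than ", min_size,
            " measured genes: ",
            paste(names(pathways)[sizes < min_size], collapse = ", "))
    present <- present[sizes >= min_size]
  }
  if (!length(present)) stop("no usable pathway")
  psizes <- lengths(present)
  usizes <- unique(psizes)
  tm <- t(mrna)
  tm_std <- scale(tm)
  sd_zero <- !is.finite(colSums(tm_std)) | apply(tm, 2, stats::sd) == 0
  tm_std[, sd_zero] <- 0
  z_std <- as.numeric(scale(z))
  r_xz <- as.numeric(crossprod(tm_std, z_std)) / (ns - 1)

  rows <- vector("list", length(lncs))
  null_nes_pool <- vector("list", length(lncs))
  for (i in seq_along(lncs)) {
    id <- lncs[i]
    y <- lnc_expr[id, samples]
    rl <- .rank_list_fast(id, y, mrna, z)
    w_all <- abs(rl$oi)^weight
    obs_pos <- lapply(present, function(g) sort(match(g, rl$mrna_id)))
    es_obs <- vapply(obs_pos, function(pos) .es_stat(pos, w_all[pos], n),
                     numeric(1))

    # null ES, one column per pathway
    null_es <- .with_seed(.key_seed(seed, id), {
      if (null_method == "geneset") {
        by_size <- lapply(usizes, function(m) .null_es(w_all, m, n, n_perm))
        names(by_size) <- as.character(usizes)
        vapply(psizes, function(m) by_size[[as.character(m)]],
               numeric(n_perm))
      } else {
        .null_es_sample_perm(y, tm_std, r_xz, z_std, present, weight,
                             n_perm)
      }
    })
    if (is.null(dim(null_es)))
      null_es <- matrix(null_es, ncol = length(present))
    colnames(null_es) <- names(present)

    # NES normalizers are shared within a pathway-size group so that
    # observed and pooled null scores stay exchangeable (a per-pathway
    # normalizer adds estimation noise that inflates the pooled tail)
    norm_of <- lapply(usizes, function(m) {
      pool <- as.numeric(null_es[, psizes == m, drop = FALSE])
      c(pos = mean(pool[pool >= 0]), neg = mean(abs(pool[pool < 0])))
    })
    names(norm_of) <- as.character(usizes)

    per_path <- lapply(seq_along(present), function(k) {
      nulls <- null_es[, k]
      nrm <- norm_of[[as.character(psizes[k])]]
      p_perm <- .nes_p(es_obs[k], nulls, n_perm)$p_perm
      nes <- if (es_obs[k] >= 0) es_obs[k] / nrm[["pos"]] else
        es_obs[k] / nrm[["neg"]]
      null_nes <- ifelse(nulls >= 0, nulls / nrm[["pos"]],
                         nulls / nrm[["neg"]])
      list(row = data.frame(lnc_id = id, pathway = names(present)[k],
                            n_hits = psizes[k], es = es_obs[k],
                            nes = nes, p_perm = p_perm,
                            stringsAsFactors = FALSE),
           null_nes = null_nes[is.finite(null_nes)])
    })
    rows[[i]] <- do.call(rbind, lapply(per_path, `[[`, "row"))
    null_nes_pool[[i]] <- unlist(lapply(per_path, `[[`, "null_nes"))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  tab$fdr <- if (fdr_method == "bh") {
    stats::p.adjust(tab$p_perm, "BH")
  } else {
    fdr <- rep(NA_real_, nrow(tab))
    for (i in seq_along(lncs)) {
      sel <- tab$lnc_id == lncs[i]
      fdr[sel] <- .pooled_nes_fdr(tab$nes[sel], null_nes_pool[[i]])
    }
    fdr
  }
  tab$fsi <- final_significance_index(tab$fdr, tab$es)
  tab$flagged <- tab$fdr < fdr_max
  tab
}

# Sample-permutation null: permute the lncRNA vector, recompute the
# purity-adjusted partial correlations, OI ranking and ES for every
# pathway. Returns an n_perm x n_pathways matrix. Inter-gene correlation
# of the mRNA matrix is preserved because only the lncRNA is permuted.
# `tm_std` / `z_std` are column-standardized so correlations reduce to
# cross-products.
.null_es_sample_perm <- function(y, tm_std, r_xz, z_std, present, weight,
                                 n_perm) {
  ns <- length(y)
  n <- ncol(tm_std)
  ids <- colnames(tm_std)
  y_std <- as.numeric(scale(y))
  Y <- vapply(seq_len(n_perm), function(b) y_std[sample.int(ns)],
              numeric(ns))
  r_xy <- crossprod(tm_std, Y) / (ns - 1)              # genes x perms
  r_yz <- as.numeric(crossprod(Y, z_std)) / (ns - 1)
  denom <- sqrt(pmax(1 - r_xz^2, 1e-12)) %o% sqrt(pmax(1 - r_yz^2, 1e-12))
  pcc <- (r_xy - r_xz %o% r_yz) / denom
  pcc[!is.finite(pcc)] <- 0
  pcc <- pmin(pmax(pcc, -1), 1)        # argument order keeps the dim
  dof <- ns - 3
  tt <- pcc * sqrt(dof / pmax(1 - pcc^2, 1e-300))
  p <- 2 * stats::pt(-abs(tt), df = dof)
  oi <- sign(pcc) * (-log10(pmax(p, 1e-320)))
  idx_sets <- lapply(present, match, table = ids)
  out <- matrix(NA_real_, n_perm, length(present))
  for (b in seq_len(n_perm)) {
    ob <- oi[, b]
    ord <- order(-ob)                    # continuous: ties negligible
    pos_of <- integer(n)
    pos_of[ord] <- seq_len(n)
    w_all <- abs(ob[ord])^weight
    for (k in seq_along(idx_sets)) {
      pos <- sort(pos_of[idx_sets[[k]]])
      out[b, k] <- .es_stat(pos, w_all[pos], n)
    }
  }
  out
}

# GSEA-style FDR: for NES* >= 0,
#   q = [#(null NES >= NES*) / #(null NES >= 0)] /
#       [#(obs NES >= NES*) / #(obs NES >= 0)], clipped to [0, 1];
# symmetric for negative scores.
.pooled_nes_fdr <- function(obs, null) {
  q <- rep(NA_real_, length(obs))
  ok <- is.finite(obs)
  for (side in c(1, -1)) {
    sel <- ok & (if (side > 0) obs >= 0 else obs < 0)
    if (!any(sel)) next
    nul <- if (side > 0) null[null >= 0] else -null[null < 0]
    ob_all <- if (side > 0) obs[ok & obs >= 0] else -obs[ok & obs < 0]
    x <- if (side > 0) obs[sel] else -obs[sel]
    nul_s <- sort(nul)
    ob_s <- sort(ob_all)
    frac_null <- if (length(nul)) {
      (length(nul) - findInterval(x, nul_s, left.open = TRUE)) / length(nul)
    } else rep(0, length(x))
    frac_obs <- (length(ob_all) - findInterval(x, ob_s, left.open = TRUE)) /
      length(ob_all)
    q[sel] <- pmin(1, frac_null / pmax(frac_obs, .Machine$double.eps))
  }
  q[!ok] <- 1
  q
}
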