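#' Build subtype marker templates
#'
#' Ranks genes by moderated t between the two subtypes and takes the top
#' `n_markers` up-regulated genes per subtype (nominal p < 0.05). Template
#' vectors follow the cosine convention: +1 at the subtype's own markers and
#' 0 elsewhere over the marker union (`signed = TRUE` in [ntp_predict()]
#' switches the other subtype's positions to -1).
#'
#' @param expr Genes x samples log-scale expression matrix.
#' @param assignments Named two-level vector (sample -> subtype).
#' @param n_markers Markers per subtype (capped at availability with a
#'   warning).
#' @return A `subtype_template`: list with `subtypes` (sorted labels),
#'   `markers` (named list of marker ids per subtype) and `template`
#'   (marker-union x subtype 0/1 matrix).
#' @export
build_templates <- function(expr, assignments, n_markers = 50) {
  .check_expr(expr)
  assignments <- assignments[names(assignments) %in% colnames(expr)]
  lev <- sort(unique(as.character(assignments)))
  if (length(lev) != 2) stop("assignments must contain exactly two subtypes")
  ga <- names(assignments)[assignments == lev[1]]
  gb <- names(assignments)[assignments == lev[2]]
  tab <- .moderated_two_group(expr, ga, gb)   # delta = lev1 - lev2

  pick <- function(up_in_first) {
    sig <- if (up_in_first) tab$t_stat > 0 & tab$p < 0.05 else
      tab$t_stat < 0 & tab$p < 0.05
    if (sum(sig) < 5)
      stop("fewer than 5 significant markers for subtype ",
           if (up_in_first) lev[1] else lev[2])
    cand <- rownames(tab)[sig]
    ord <- order(-abs(tab$t_stat[sig]), cand)
    if (length(cand) < n_markers)
      warning("only ", length(cand), " markers available for subtype ",
              if (up_in_first) lev[1] else lev[2],
              " (requested ", n_markers, ")")
    cand[ord][seq_len(min(n_markers, length(cand)))]
  }
  markers <- list(pick(TRUE), pick(FALSE))
  names(markers) <- lev
  union <- c(markers[[1]], markers[[2]])
  template <- cbind(as.numeric(union %in% markers[[1]]),
                    as.numeric(union %in% markers[[2]]))
  dimnames(template) <- list(union, lev)
  out <- list(subtypes = lev, markers = markers, template = template)
  class(out) <- "subtype_template"
  out
}

#' Nearest template prediction with permutation confidence
#'
#' Z-scores each gene across the new cohort's samples (or uses supplied
#' `center`/`scale`, which makes single-sample prediction identical to batch
#' prediction), computes the cosine distance of each sample to each subtype
#' template over the marker union, assigns the nearest subtype, and derives
#' a permutation p-value as the add-one fraction of `n_perm` random marker
#' sets (same sizes, drawn from the measured genes) achieving a distance at
#' most as small as the observed one. BH FDR across samples; samples with
#' FDR above `fdr_exclude` are flagged excluded.
#'
#' @param expr_new Genes x samples matrix of the cohort to classify.
#' @param template A `subtype_template` from [build_templates()].
#' @param n_perm Number of random marker sets (default 1000).
#' @param fdr_exclude Exclusion threshold on the BH FDR (default 0.2).
#' @param seed Integer seed; each sample gets its own RNG stream keyed by
#'   its id so predictions do not depend on sample order.
#' @param signed If `TRUE`, use signed templates (+1 own markers, -1 other).
#' @param center,scale Optional named per-gene means and SDs for the
#'   z-scoring step (defaults computed from `expr_new`).
#' @return Data frame: `sample`, `label`, `distance`, `p`, `fdr`,
#'   `excluded`.
#' @export
ntp_predict <- function(expr_new, template, n_perm = 1000, fdr_exclude = 0.2,
                        seed = 1, signed = FALSE, center = NULL,
                        scale = NULL) {
  stopifnot(inherits(template, "subtype_template"))
  .check_expr(expr_new, "expr_new")
  union <- rownames(template$template)
  present <- intersect(union, rownames(expr_new))
  if (length(present) < 0.5 * length(union))
    stop("fewer than 50% of template markers measured; missing: ",
         paste(utils::head(setdiff(union, rownames(expr_new)), 10),
               collapse = ", "))
  if (length(present) < length(union))
    message("dropping ", length(union) - length(present),
            " template marker(s) absent from the new cohort")

  tmpl <- template$template[present, , drop = FALSE]
  if (signed) tmpl <- 2 * tmpl - 1
  if (is.null(center)) center <- rowMeans(expr_new)
  if (is.null(scale)) scale <- apply(expr_new, 1, stats::sd)
  scale <- ifelse(scale > 0, scale, 1)
  z <- (expr_new - center[rownames(expr_new)]) / scale[rownames(expr_new)]

  cos_dist <- function(v, t) {
    nv <- sqrt(sum(v^2)); nt <- sqrt(sum(t^2))
    if (nv == 0 || nt == 0) return(1)
    1 - sum(v * t) / (nv * nt)
  }
  sizes <- lengths(lapply(template$markers, intersect, y = present))
  all_genes <- rownames(z)

  res <- lapply(colnames(z), function(s) {
    v <- z[present, s]
    d <- vapply(seq_len(ncol(tmpl)), function(j) cos_dist(v, tmpl[, j]),
                numeric(1))
    names(d) <- colnames(tmpl)
    if (d[1] == d[2]) message("distance tie for sample ", s,
                              "; assigning lexicographically first subtype")
    j <- which.min(d)                     # ties -> first (sorted labels)
    d_obs <- d[j]
    null_d <- .with_seed(.key_seed(seed, s), {
      vapply(seq_len(n_perm), function(b) {
        rnd <- sample(all_genes, sum(sizes))
        own <- rnd[seq_len(sizes[j])]
        t_rnd <- if (signed) ifelse(rnd %in% own, 1, -1) else
          as.numeric(rnd %in% own)
        cos_dist(z[rnd, s], t_rnd)
      }, numeric(1))
    })
    data.frame(sample = s, label = names(d)[j], distance = unname(d_obs),
               p = (1 + sum(null_d <= d_obs)) / (n_perm + 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p, "BH")
  out$excluded <- out$fdr > fdr_exclude
  out
}
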