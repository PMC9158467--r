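# Independent oracles, deliberately naive: each walks the definition
# step by step and is kept free of the package's internals.

# ssGSEA integrated walk, one sample / one set, position by position
oracle_ssgsea <- function(values, ids, set, alpha) {
  ord <- order(-values, ids)
  ranked <- ids[ord]
  n <- length(ranked)
  rank_stat <- n:1
  hit <- ranked %in% set
  w <- abs(rank_stat)^alpha
  p_hit <- cumsum(ifelse(hit, w, 0)) / sum(w[hit])
  p_miss <- cumsum(!hit) / sum(!hit)
  sum(p_hit - p_miss)
}

# signed max deviation of the weighted KS walk, full cumulative version
oracle_es <- function(oi_sorted, hit, weight = 1) {
  n <- length(oi_sorted)
  w <- abs(oi_sorted)^weight
  inc <- ifelse(hit, w / sum(w[hit]), 0)
  dec <- ifelse(hit, 0, 1 / sum(!hit))
  walk <- cumsum(inc - dec)
  i <- which.max(abs(walk))
  if (abs(max(walk)) == abs(min(walk))) return(max(walk))  # tie -> positive
  walk[i]
}

# all-pairs Harrell C with explicit double loop
oracle_cindex <- function(score, time, event) {
  num <- 0
  den <- 0
  n <- length(score)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (time[i] < time[j] && event[i] == 1) {
        den <- den + 1
        if (score[i] > score[j]) num <- num + 1
        else if (score[i] == score[j]) num <- num + 0.5
      }
    }
  }
  num / den
}

# partial correlation via residual regression
oracle_partial_cor <- function(x, y, z) {
  rx <- stats::resid(stats::lm(x ~ z))
  ry <- stats::resid(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

# Mann-Whitney AUC (higher score in cases)
oracle_rank_auc <- function(cases, controls) {
  cmp <- outer(cases, controls, ">") + 0.5 * outer(cases, controls, "==")
  mean(cmp)
}

# small labelled expression matrix helper
rand_expr <- function(n_genes, n_samples, seed = 1, prefix = "G") {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  dimnames(m) <- list(sprintf("%s%03d", prefix, seq_len(n_genes)),
                      sprintf("S%03d", seq_len(n_samples)))
  m
}

# survival table from explicit vectors
surv_df <- function(time, event, samples = sprintf("S%03d", seq_along(time))) {
  data.frame(sample = samples, time = time, event = event,
             stringsAsFactors = FALSE)
}

# map arbitrary cluster labels onto reference labels by majority vote
match_labels <- function(pred, ref) {
  tab <- table(pred, ref)
  map <- colnames(tab)[apply(tab, 1, which.max)]
  names(map) <- rownames(tab)
  unname(map[as.character(pred)])
}
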