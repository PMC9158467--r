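# exact-correlation construction: orthonormal basis via QR
ortho_basis <- function(n, k, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * k), n, k))))
  q <- q[, -1, drop = FALSE]    # orthonormal and centered (orthogonal to 1)
  sweep(q, 2, apply(q, 2, sd), "/")
}

test_that("partial correlation reduces to Pearson when purity is orthogonal", {
  b <- ortho_basis(60, 3, seed = 1)
  x <- b[, 1]
  y <- 0.8 * b[, 1] + sqrt(1 - 0.64) * b[, 2]
  z <- b[, 3]                            # orthogonal to both
  rec <- purity_adjusted_association(y, x, z)
  expect_equal(rec$pcc, stats::cor(x, y), tolerance = 1e-10)
  expect_equal(rec$dof, 57)
})

test_that("the worked partial-correlation example gives 0.55/0.75", {
  b <- ortho_basis(120, 3, seed = 2)
  z <- b[, 1]
  x <- 0.5 * z + sqrt(0.75) * b[, 2]
  cc <- 0.55 / sqrt(0.75)
  y <- 0.5 * z + cc * b[, 2] + sqrt(0.75 - cc^2) * b[, 3]
  rec <- purity_adjusted_association(y, x, z)
  expect_equal(stats::cor(x, y), 0.8, tolerance = 1e-10)
  expect_equal(rec$pcc, 0.55 / 0.75, tolerance = 1e-8)
})

test_that("partial correlation matches the residual-regression oracle", {
  set.seed(3)
  for (i in 1:300) {
    n <- sample(10:40, 1)
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    y <- -0.3 * z + 0.2 * x + rnorm(n)
    rec <- purity_adjusted_association(y, x, z)
    expect_equal(rec$pcc, oracle_partial_cor(x, y, z), tolerance = 1e-10)
  }
})

test_that("partial correlation rejects degenerate inputs", {
  z <- rnorm(20)
  x <- rnorm(20)
  expect_error(purity_adjusted_association(rep(1, 20), x, z), "constant")
  expect_error(purity_adjusted_association(x[1:10], x, z), "equal length")
  expect_error(purity_adjusted_association(z, x, z), "perfectly correlated")
  expect_error(purity_adjusted_association(x[1:4], x[1:4], z[1:4]),
               "at least 5")
})

test_that("rank lists order by OI, reverse under negation, and cap p = 0", {
  set.seed(4)
  mrna <- rand_expr(50, 30, seed = 4, prefix = "M")
  lnc <- rand_expr(3, 30, seed = 5, prefix = "L")
  pur <- stats::setNames(runif(30, 0.4, 1), colnames(mrna))
  rl <- build_rank_list("L001", mrna, lnc, pur)
  expect_s3_class(rl, "ranked_list")
  expect_identical(attr(rl, "lnc_id"), "L001")
  expect_true(all(diff(rl$oi) <= 0))
  # sign symmetry: negating the lncRNA reverses the ranking exactly
  lnc_neg <- lnc
  lnc_neg["L001", ] <- -lnc_neg["L001", ]
  rl_neg <- build_rank_list("L001", mrna, lnc_neg, pur)
  expect_identical(rl_neg$mrna_id, rev(rl$mrna_id))
  expect_equal(rl_neg$oi, -rev(rl$oi), tolerance = 1e-10)
  # an mRNA identical to the lncRNA tops the list with capped OI
  mrna2 <- rbind(mrna, COPY = lnc["L001", ])
  expect_warning(rl2 <- build_rank_list("L001", mrna2, lnc, pur), "capped")
  expect_identical(rl2$mrna_id[1], "COPY")
  expect_equal(rl2$oi[1], 320)
})

test_that("enrichment walk matches the hand-stepped 4-gene examples", {
  oi <- stats::setNames(c(2, 1, -1, -2), c("A", "B", "C", "D"))
  res_a <- preranked_gsea(oi, "A", weight = 1, n_perm = 10, seed = 1,
                          min_size = 1)
  expect_equal(res_a$es, 1, tolerance = 1e-12)
  res_d <- preranked_gsea(oi, "D", weight = 1, n_perm = 10, seed = 1,
                          min_size = 1)
  expect_equal(res_d$es, -1, tolerance = 1e-12)
  expect_error(preranked_gsea(oi, c("A", "B", "C", "D"), min_size = 1),
               "no misses")
  expect_error(preranked_gsea(oi, c("X", "Y"), min_size = 1), "no genes")
})

test_that("enrichment score matches the naive cumulative-walk oracle", {
  set.seed(5)
  for (i in 1:40) {
    n <- sample(20:120, 1)
    oi <- sort(rnorm(n, sd = 2), decreasing = TRUE)
    names(oi) <- sprintf("G%03d", seq_len(n))
    m <- sample(3:10, 1)
    hit_ids <- sample(names(oi), m)
    w <- sample(c(0.5, 1, 2), 1)
    res <- preranked_gsea(oi, hit_ids, weight = w, n_perm = 5, seed = i,
                          min_size = 1)
    expect_equal(res$es, oracle_es(oi, names(oi) %in% hit_ids, w),
                 tolerance = 1e-12)
  }
})

test_that("enrichment score agrees with fgsea's statistic", {
  skip_if_not_installed("fgsea")
  set.seed(6)
  for (i in 1:20) {
    n <- 150
    stats_vec <- sort(rnorm(n, sd = 3), decreasing = TRUE)
    names(stats_vec) <- sprintf("G%03d", seq_len(n))
    pos <- sort(sample(n, 12))
    ours <- preranked_gsea(stats_vec, names(stats_vec)[pos], weight = 1,
                           n_perm = 5, seed = i, min_size = 1)$es
    theirs <- fgsea::calcGseaStat(stats_vec, pos, gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
})

test_that("ES is antisymmetric under list reversal with negated OI", {
  set.seed(7)
  for (i in 1:20) {
    n <- 60
    oi <- sort(rnorm(n, sd = 2), decreasing = TRUE)
    names(oi) <- sprintf("G%03d", seq_len(n))
    ids <- sample(names(oi), 8)
    es_fwd <- preranked_gsea(oi, ids, n_perm = 5, seed = 1, min_size = 1)$es
    es_rev <- preranked_gsea(rev(-oi), ids, n_perm = 5, seed = 1,
                             min_size = 1)$es
    expect_equal(es_rev, -es_fwd, tolerance = 1e-12)
  }
})

test_that("the final significance index obeys its algebra", {
  expect_equal(final_significance_index(0, 0.6), 1)
  expect_equal(final_significance_index(0.5, -2), 0)
  expect_equal(final_significance_index(0.25, -0.3), -0.5)
  expect_equal(final_significance_index(0.1, 0), 0)
  expect_error(final_significance_index(1.2, 1), "\\[0, 1\\]")
  # monotone decreasing in fdr for positive es; always within [-1, 1]
  f <- final_significance_index(seq(0, 1, 0.05), 1)
  expect_true(all(diff(f) < 0))
  expect_true(all(abs(f) <= 1))
})

test_that("run_prolnc output satisfies its invariants and recovers planted pairs", {
  gs <- generate_gene_sets(2, 10, 80, seed = 1)
  co <- generate_cohort(gs, n_samples = 120, subtype_shift = 1,
                        modulator_frac = 0.5, n_lnc = 16,
                        modulator_weight = 0.9, seed = 20)
  pr <- suppressWarnings(run_prolnc(co$lnc, co$mrna, co$truth$purity, gs,
                                    n_perm = 150, seed = 3))
  expect_identical(nrow(pr), 32L)
  expect_true(all(abs(pr$fsi) <= 1))
  expect_true(all(pr$fdr >= 0 & pr$fdr <= 1))
  sel <- pr$fdr < 0.5
  expect_true(all(sign(pr$fsi[sel]) == sign(pr$es[sel])))
  expect_true(all(pr$fsi[pr$fdr == 0.5] == 0))
  # flagged rows respect |fsi| > 1 - 2 * fdr_max by construction
  expect_true(all(abs(pr$fsi[pr$flagged]) > 1 - 2 * 0.001))
  truthp <- paste(co$truth$modulator_pairs$lnc_id,
                  co$truth$modulator_pairs$pathway)
  planted <- paste(pr$lnc_id, pr$pathway) %in% truthp
  expect_gt(mean(pr$flagged[planted]), 0.7)
  null_lnc <- !(pr$lnc_id %in% co$truth$modulator_pairs$lnc_id)
  expect_lte(sum(pr$flagged[null_lnc]), 1)
})

test_that("run_prolnc results are independent of lncRNA order", {
  gs <- generate_gene_sets(2, 8, 40, seed = 2)
  co <- generate_cohort(gs, n_samples = 60, modulator_frac = 0.5,
                        n_lnc = 8, seed = 21)
  pr1 <- suppressWarnings(run_prolnc(co$lnc, co$mrna, co$truth$purity, gs,
                                     n_perm = 50, seed = 9))
  shuffle <- rev(rownames(co$lnc))
  pr2 <- suppressWarnings(run_prolnc(co$lnc[shuffle, ], co$mrna,
                                     co$truth$purity, gs,
                                     n_perm = 50, seed = 9))
  key1 <- paste(pr1$lnc_id, pr1$pathway)
  key2 <- paste(pr2$lnc_id, pr2$pathway)
  expect_setequal(key1, key2)
  m <- match(key1, key2)
  expect_equal(pr1$es, pr2$es[m], tolerance = 1e-12)
  expect_equal(pr1$p_perm, pr2$p_perm[m], tolerance = 1e-12)
  expect_equal(pr1$fdr, pr2$fdr[m], tolerance = 1e-12)
})

test_that("the gene-set null variant runs and keeps the same observed ES", {
  gs <- generate_gene_sets(2, 8, 40, seed = 3)
  co <- generate_cohort(gs, n_samples = 60, modulator_frac = 0.5,
                        n_lnc = 6, seed = 22)
  pr_s <- suppressWarnings(run_prolnc(co$lnc, co$mrna, co$truth$purity, gs,
                                      n_perm = 40, seed = 4))
  pr_g <- suppressWarnings(run_prolnc(co$lnc, co$mrna, co$truth$purity, gs,
                                      n_perm = 40, seed = 4,
                                      null_method = "geneset"))
  expect_equal(pr_s$es, pr_g$es, tolerance = 1e-12)
})
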