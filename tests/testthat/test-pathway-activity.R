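test_that("ssGSEA score matches the hand-stepped walk on a 3-gene list", {
  expr <- matrix(c(3, 2, 1), 3, 1, dimnames = list(c("A", "B", "C"), "S1"))
  expr <- cbind(expr, S2 = c(3, 2, 1))
  sc <- score_gene_sets(expr, list(SET = "A"), alpha = 0, min_size = 1)
  # walk: (P_hit - P_miss) = (1, 0.5, 0) -> 1.5
  expect_equal(sc["SET", "S1"], 1.5, tolerance = 1e-12)
  # identical expression columns give identical scores
  expect_equal(sc[, "S1"], sc[, "S2"], tolerance = 1e-12)
})

test_that("ssGSEA agrees with the naive positional oracle", {
  expr <- rand_expr(40, 6, seed = 2)
  sets <- list(A = rownames(expr)[c(3, 9, 17, 21, 30)],
               B = rownames(expr)[c(1, 2, 4, 11, 18, 25, 33)])
  for (alpha in c(0, 0.25, 1)) {
    sc <- score_gene_sets(expr, sets, alpha = alpha, min_size = 1)
    for (s in colnames(expr)) {
      for (nm in names(sets)) {
        expect_equal(sc[nm, s],
                     oracle_ssgsea(expr[, s], rownames(expr), sets[[nm]], alpha),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("degenerate gene sets are dropped with warnings", {
  expr <- rand_expr(10, 4, seed = 3)
  expect_warning(
    sc <- score_gene_sets(expr, list(ALL = rownames(expr),
                                     OK = rownames(expr)[1:6]),
                          min_size = 5),
    "all genes")
  expect_identical(rownames(sc), "OK")
  expect_warning(
    score_gene_sets(expr, list(TINY = rownames(expr)[1:2],
                               OK = rownames(expr)[1:6]), min_size = 5),
    "fewer than 5")
  expect_error(score_gene_sets(expr, list(MISSING = c("x", "y"))),
               "no gene set overlaps")
})

test_that("scoring is invariant to monotone transforms of a sample", {
  expr <- rand_expr(50, 3, seed = 4)
  sets <- list(S = rownames(expr)[1:8])
  base <- score_gene_sets(expr, sets)
  expr2 <- expr
  expr2[, 2] <- exp(expr2[, 2] / 2)       # strictly monotone
  expect_equal(score_gene_sets(expr2, sets)[, 2], base[, 2],
               tolerance = 1e-12)
})

test_that("normalization rescales by the global score range", {
  expr <- rand_expr(50, 5, seed = 5)
  sets <- list(A = rownames(expr)[1:8], B = rownames(expr)[9:20])
  raw <- score_gene_sets(expr, sets, normalize = FALSE)
  nrm <- score_gene_sets(expr, sets, normalize = TRUE)
  expect_equal(nrm, raw / (max(raw) - min(raw)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("gsva-like variant standardizes genes and reports max deviation", {
  expr <- rand_expr(60, 8, seed = 6)
  sets <- list(S = rownames(expr)[1:10])
  sc <- score_gene_sets(expr, sets, method = "gsva")
  expect_identical(attr(sc, "method"), "gsva")
  expect_true(all(abs(sc) <= 1))
  # shifting/scaling all genes of one sample changes nothing after
  # row standardization only if applied to a whole row; a row-wise shift
  # leaves scores identical
  expr2 <- expr + 5
  expect_equal(score_gene_sets(expr2, sets, method = "gsva"), sc,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("differential activity detects a planted shift and rejects overlap", {
  set.seed(7)
  act <- rand_expr(20, 40, seed = 7, prefix = "PW")
  a <- colnames(act)[1:20]
  b <- colnames(act)[21:40]
  act["PW005", b] <- act["PW005", b] + 2
  res <- differential_activity(act, a, b)
  expect_identical(res$set_name[which.min(res$p)], "PW005")
  expect_lt(res$fdr[res$set_name == "PW005"], 0.01)
  expect_error(differential_activity(act, a, c(a[1], b[-1])), "disjoint")
  expect_error(differential_activity(act, a[1:2], b), "at least 3")
})

test_that("constant activity rows give t = 0 and p = 1", {
  act <- rand_expr(5, 12, seed = 8, prefix = "PW")
  act[2, ] <- 3.14
  res <- differential_activity(act, colnames(act)[1:6], colnames(act)[7:12])
  expect_equal(res$t_stat[2], 0)
  expect_equal(res$p[2], 1)
})

test_that("label permutation keeps differential-activity discoveries near zero", {
  act <- rand_expr(30, 40, seed = 9, prefix = "PW")
  set.seed(10)
  frac <- vapply(1:30, function(i) {
    idx <- sample(colnames(act))
    res <- differential_activity(act, idx[1:20], idx[21:40])
    mean(res$fdr < 0.05)
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})

test_that("km_optimal_cutoff separates planted hazard groups", {
  set.seed(11)
  n <- 80
  score <- c(rnorm(n / 2, 0), rnorm(n / 2, 6))   # two well-separated groups
  time <- c(rexp(n / 2, 0.01), rexp(n / 2, 0.08))
  surv <- surv_df(time, rep(1, n))
  res <- suppressMessages(km_optimal_cutoff(score, surv))
  expect_gt(res$cutoff, max(score[1:(n / 2)]) - 3)
  expect_lt(res$cutoff, min(score[(n / 2 + 1):n]) + 3)
  expect_lt(res$p, 1e-4)

  expect_error(suppressMessages(
    km_optimal_cutoff(rep(1, n), surv)), "no admissible cutoff")
  expect_error(suppressMessages(
    km_optimal_cutoff(score, surv_df(time, rep(0, n)))), "no events")
})

test_that("min_prop = 0.5 admits only the median split", {
  set.seed(12)
  score <- seq_len(20)
  surv <- surv_df(rexp(20, 0.05) + 0.1, rep(1, 20))
  res <- suppressMessages(km_optimal_cutoff(score, surv, min_prop = 0.5))
  expect_equal(res$cutoff, 10)          # the unique 10/10 split
  # with odd n both strata cannot reach half the samples
  surv21 <- surv_df(rexp(21, 0.05) + 0.1, rep(1, 21))
  expect_error(suppressMessages(
    km_optimal_cutoff(seq_len(21), surv21, min_prop = 0.5)),
    "no admissible cutoff")
})
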