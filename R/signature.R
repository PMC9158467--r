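#' Fit a LASSO-Cox risk signature
#'
#' L1-penalized Cox regression over a log-spaced lambda path with k-fold
#' cross-validation (folds stratified by event status, assignment fixed by
#' the seed); the optimal lambda minimizes the mean cross-validated partial
#' likelihood deviance, and the stored model keeps only the features with
#' non-zero coefficient at that lambda (coefficients on the original
#' expression scale).
#'
#' @param X Samples x features numeric matrix (rownames = sample ids).
#' @param surv Survival data frame (`sample`, `time`, `event`).
#' @param n_folds Number of CV folds (default 10).
#' @param lambda_grid Optional decreasing lambda sequence (glmnet
#'   auto-scales a 100-value path from the data when absent).
#' @param seed Integer seed controlling fold assignment.
#' @param rule `"min"` (deviance minimum, default) or `"1se"`.
#' @return A `signature_model`: list with `features`, `coefficients`,
#'   `lambda_opt`, `cv_curve` (data.frame lambda/deviance/se) and `fit`
#'   (the full-data glmnet path).
#' @export
fit_lasso_cox <- function(X, surv, n_folds = 10, lambda_grid = NULL,
                          seed = 1, rule = c("min", "1se")) {
  rule <- match.arg(rule)
  .check_surv(surv)
  if (!is.matrix(X) || is.null(colnames(X)))
    stop("`X` must be a samples x features matrix with feature colnames")
  if (ncol(X) < 2) stop("need at least 2 features")
  if (!is.null(rownames(X)) && all(surv$sample %in% rownames(X)))
    X <- X[surv$sample, , drop = FALSE]
  if (nrow(X) != nrow(surv)) stop("X rows must match survival samples")
  events <- sum(surv$event)
  if (events < n_folds) stop("need at least n_folds events")

  y <- survival::Surv(surv$time, surv$event)
  foldid <- .with_seed(seed, {
    f <- integer(nrow(surv))
    for (e in c(0, 1)) {
      idx <- sample(which(surv$event == e))
      f[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    f
  })
  cv <- glmnet::cv.glmnet(X, y, family = "cox", foldid = foldid,
                          lambda = lambda_grid, standardize = TRUE)
  lambda_opt <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  cf <- as.numeric(stats::coef(cv, s = lambda_opt))
  names(cf) <- colnames(X)
  active <- cf[cf != 0]
  if (!length(active))
    warning("all coefficients shrunk to zero at the optimal lambda")
  model <- list(features = names(active), coefficients = unname(active),
                lambda_opt = lambda_opt,
                cv_curve = data.frame(lambda = cv$lambda, deviance = cv$cvm,
                                      se = cv$cvsd),
                fit = cv$glmnet.fit)
  class(model) <- "signature_model"
  model
}

#' @rdname fit_lasso_cox
#' @param x A `signature_model`.
#' @param ... Unused.
#' @method print signature_model
#' @export
print.signature_model <- function(x, ...) {
  cat("LASSO-Cox signature:", length(x$features), "feature(s), lambda =",
      signif(x$lambda_opt, 3), "\n")
  if (length(x$features))
    print(stats::setNames(round(x$coefficients, 4), x$features))
  invisible(x)
}

#' Compute per-sample risk scores from a signature model
#'
#' Linear predictor `sum_i coef_i * x_i` with no intercept; an empty model
#' scores every sample 0.
#'
#' @param X Samples x features matrix containing every model feature.
#' @param model A `signature_model`.
#' @return Named numeric vector of risk scores.
#' @export
compute_risk_score <- function(X, model) {
  stopifnot(inherits(model, "signature_model"))
  if (!length(model$features))
    return(stats::setNames(rep(0, nrow(X)), rownames(X)))
  missing <- setdiff(model$features, colnames(X))
  if (length(missing))
    stop("features missing from X: ", paste(missing, collapse = ", "))
  score <- as.numeric(X[, model$features, drop = FALSE] %*%
                        model$coefficients)
  stats::setNames(score, rownames(X))
}

#' Multivariate Cox model of a risk score with clinical covariates
#'
#' Fits `Surv ~ score + covariates` (Breslow ties), reporting the adjusted
#' hazard ratio, 95% CI and p for every term. Constant covariate columns
#' are dropped with a warning; an exactly collinear pair (|r| = 1) is an
#' error.
#'
#' @param score Per-sample numeric vector (named or aligned with `surv`).
#' @param covariates Data frame of covariates aligned with `surv` rows (or
#'   with a `sample` column to merge on).
#' @param surv Survival data frame.
#' @return Data frame: `term`, `beta`, `hr`, `hr_lower`, `hr_upper`, `se`,
#'   `z`, `p`, `converged`.
#' @export
multivariate_cox <- function(score, covariates, surv) {
  .check_surv(surv)
  score <- .align_score(score, surv)
  if (!is.data.frame(covariates)) covariates <- as.data.frame(covariates)
  if ("sample" %in% names(covariates)) {
    covariates <- covariates[match(surv$sample, covariates$sample), ,
                             drop = FALSE]
    covariates$sample <- NULL
  }
  if (nrow(covariates) != nrow(surv))
    stop("covariates must align with survival rows")

  num <- vapply(covariates, is.numeric, logical(1))
  const <- vapply(covariates, function(v) length(unique(v)) <= 1, logical(1))
  if (any(const)) {
    warning("dropping constant covariate(s): ",
            paste(names(covariates)[const], collapse = ", "))
    covariates <- covariates[!const]
    num <- num[!const]
  }
  mm <- cbind(score = score,
              if (ncol(covariates))
                stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE])
  cc <- suppressWarnings(stats::cor(mm))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 0
  if (any(abs(cc) >= 1 - 1e-12)) {
    bad <- which(abs(cc) >= 1 - 1e-12, arr.ind = TRUE)[1, ]
    stop("collinear terms: ", colnames(mm)[bad[1]], " and ",
         colnames(mm)[bad[2]])
  }

  df <- data.frame(mm, check.names = TRUE)
  df$.time <- surv$time
  df$.event <- surv$event
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ . - .time - .event,
                    data = df, ties = "breslow"),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  data.frame(term = rownames(co), beta = co[, "coef"],
             hr = co[, "exp(coef)"],
             hr_lower = ci[, "lower .95"], hr_upper = ci[, "upper .95"],
             se = co[, "se(coef)"], z = co[, "z"], p = co[, "Pr(>|z|)"],
             converged = converged & abs(co[, "coef"]) <= 20,
             stringsAsFactors = FALSE, row.names = NULL)
}
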