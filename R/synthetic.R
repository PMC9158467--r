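#' Generate disjoint pathway gene sets plus a background pool
#'
#' Builds a synthetic stand-in for a curated pathway collection: `n_pathways`
#' disjoint sets of `genes_per_pathway` genes, plus `n_background` genes that
#' belong to no set.
#'
#' @param n_pathways Number of pathways (>= 1).
#' @param genes_per_pathway Genes per pathway (>= 1).
#' @param n_background Background genes outside every set (>= 0).
#' @param seed Integer seed (identifier layout is deterministic; the seed is
#'   recorded for provenance).
#' @return A `gene_set_collection`: list with `sets` (named list of gene id
#'   vectors), `background` (character vector) and `seed`.
#' @examples
#' gs <- generate_gene_sets(7, 50, 2000, seed = 1)
#' lengths(gs$sets)
#' @export
generate_gene_sets <- function(n_pathways, genes_per_pathway, n_background,
                               seed = 1) {
  if (n_pathways < 1 || genes_per_pathway < 1)
    stop("n_pathways and genes_per_pathway must be >= 1")
  if (n_background < 0) stop("n_background must be >= 0")
  n_in <- n_pathways * genes_per_pathway
  ids <- sprintf("MRNA%05d", seq_len(n_in + n_background))
  sets <- split(ids[seq_len(n_in)],
                rep(seq_len(n_pathways), each = genes_per_pathway))
  names(sets) <- sprintf("PATHWAY%02d", seq_len(n_pathways))
  out <- list(sets = sets,
              background = if (n_background > 0) ids[-seq_len(n_in)] else character(0),
              seed = as.integer(seed))
  class(out) <- "gene_set_collection"
  out
}

#' Simulate one bulk expression cohort with planted ground truth
#'
#' Emulates, on the log2 scale, a tumor cohort whose samples fall into two
#' subtypes defined by the activity of correlated pathway gene modules, with
#' lncRNAs that are (i) true pathway modulators confounded by tumor purity
#' and (ii) carriers of planted proportional-hazards effects on survival.
#'
#' The expression model is Gaussian on the log2 scale. Pathway gene g in
#' pathway p for sample s is
#' `mu_g + shift * I(S2) + w_pur * purity_z + sqrt(rho) * Z_p + sqrt(1-rho) * e`,
#' so the subtype mean difference is `subtype_shift` within-group SD units
#' and genes within a pathway share the latent factor `Z_p`. Modulator
#' lncRNAs are `a * pathway_mean_z + b * purity_z + noise`; non-modulators
#' get only the purity term, so naive correlations with pathways are inflated
#' through purity and the partial-correlation adjustment is falsifiable.
#' Survival is exponential proportional hazards on the standardized planted
#' lncRNAs (plus a weak age effect), with independent uniform censoring on
#' `(0, tau)` where tau is solved numerically for the requested censoring
#' fraction.
#'
#' @param gene_sets A `gene_set_collection` from [generate_gene_sets()].
#' @param n_samples Number of samples (>= 10).
#' @param subtype_shift Subtype mean shift for pathway genes, in SD units.
#' @param modulator_frac Fraction of lncRNAs planted as pathway modulators.
#' @param n_lnc Number of lncRNAs.
#' @param hazard_beta Absolute log-hazard of planted prognostic lncRNAs
#'   (applied to their standardized expression; 70% risk, 30% protective).
#' @param censor_rate Target censoring fraction in `[0, 1)`; 0 disables
#'   censoring.
#' @param seed Integer seed.
#' @param n_prognostic Number of prognostic lncRNAs (taken from the
#'   modulators first so they survive the pipeline's intersection step).
#' @param modulator_weight Mixture weight `a` on the standardized pathway
#'   mean.
#' @param purity_weight Loading `b` of every lncRNA on standardized purity.
#' @param pathway_cor Intra-pathway gene correlation `rho`.
#' @param pathway_purity_weight Loading of pathway genes on purity.
#' @param baseline_median Baseline survival median in months (exponential).
#' @param age_beta Log-hazard per year of the simulated age covariate.
#' @param cohort_id Prefix for sample identifiers.
#' @return List with elements `mrna` and `lnc` (log2 expression matrices,
#'   genes x samples), `surv` (data.frame: sample, time, event, age) and
#'   `truth` (a `cohort_truth`: subtype map, modulator pairs, prognostic
#'   coefficients, purity, seed).
#' @export
generate_cohort <- function(gene_sets, n_samples = 200, subtype_shift = 2,
                            modulator_frac = 0.2, n_lnc = 200,
                            hazard_beta = 0.8, censor_rate = 0.35, seed = 1,
                            n_prognostic = 10, modulator_weight = 0.8,
                            purity_weight = 0.6, pathway_cor = 0.5,
                            pathway_purity_weight = 0.4,
                            baseline_median = 60, age_beta = 0.02,
                            cohort_id = "C1") {
  sets <- .as_sets(gene_sets)
  if (n_samples < 10) stop("n_samples must be >= 10")
  if (modulator_frac < 0 || modulator_frac > 1)
    stop("modulator_frac must be in [0, 1]")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)")
  if (n_lnc < 1) stop("n_lnc must be >= 1")
  set.seed(seed)

  n_path <- length(sets)
  samples <- sprintf("%s_S%04d", cohort_id, seq_len(n_samples))
  subtype <- sample(rep(c("S1", "S2"), length.out = n_samples))
  names(subtype) <- samples
  s2 <- as.numeric(subtype == "S2")

  purity <- stats::rbeta(n_samples, 8, 3)
  names(purity) <- samples
  pur_z <- as.numeric(scale(purity))

  genes <- c(unlist(sets, use.names = FALSE),
             if (inherits(gene_sets, "gene_set_collection")) gene_sets$background else character(0))
  genes <- unique(genes)
  n_genes <- length(genes)
  mu_g <- stats::rnorm(n_genes, mean = 7, sd = 1)
  names(mu_g) <- genes
  Z <- matrix(stats::rnorm(n_samples * n_path), n_samples, n_path)

  mrna <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples,
                 dimnames = list(genes, samples))
  in_path <- rep(0L, n_genes)
  names(in_path) <- genes
  for (p in seq_len(n_path)) in_path[sets[[p]]] <- p
  for (p in seq_len(n_path)) {
    idx <- which(in_path == p)
    sig <- subtype_shift * s2 + pathway_purity_weight * pur_z +
      sqrt(pathway_cor) * Z[, p]
    mrna[idx, ] <- sqrt(1 - pathway_cor) * mrna[idx, ] +
      matrix(sig, length(idx), n_samples, byrow = TRUE)
  }
  mrna <- mrna + mu_g

  # deterministic planted-lncRNA layout: first round(frac * n) lncRNAs are
  # modulators, pathway assignment cycles; prognostic ids come first so they
  # are shared across cohorts generated with the same arguments
  lnc_ids <- sprintf("LNC%04d", seq_len(n_lnc))
  n_mod <- round(modulator_frac * n_lnc)
  mod_ids <- lnc_ids[seq_len(n_mod)]
  mod_path <- names(sets)[((seq_len(n_mod) - 1L) %% n_path) + 1L]
  # tumor-intrinsic pathway activity: the pathway mean with its purity
  # component removed (modulator lncRNAs track the biology, while the
  # measured values of both sides still carry the purity confounder)
  path_mean_z <- vapply(seq_len(n_path), function(p) {
    pm <- colMeans(mrna[sets[[p]], , drop = FALSE]) -
      pathway_purity_weight * pur_z
    as.numeric(scale(pm))
  }, numeric(n_samples))

  # planted prognostic layout first: protective lncRNAs couple negatively
  # to their pathway so their survival direction is consistent with the
  # proliferative axis (a lncRNA low in the aggressive subtype protects)
  n_prog <- min(n_prognostic, n_lnc)
  prog_ids <- if (n_mod >= n_prog) mod_ids[seq_len(n_prog)] else
    lnc_ids[seq_len(n_prog)]
  n_risk <- ceiling(0.7 * n_prog)
  betas <- rep(c(hazard_beta, -hazard_beta), c(n_risk, n_prog - n_risk))
  names(betas) <- prog_ids
  if (!all(is.finite(betas))) stop("planted hazard coefficients must be finite")
  coupling <- rep(1, n_lnc)
  names(coupling) <- lnc_ids
  coupling[prog_ids] <- ifelse(betas >= 0 | hazard_beta == 0, 1, -1)

  # intrinsic (tumor-cell) lncRNA component; the measured value adds the
  # purity confounder on top
  mu_l <- stats::rnorm(n_lnc, mean = 5, sd = 1)
  intr <- matrix(stats::rnorm(n_lnc * n_samples), n_lnc, n_samples,
                 dimnames = list(lnc_ids, samples))
  if (n_mod > 0) {
    noise_sd <- sqrt(max(0.04, 1 - modulator_weight^2))
    for (i in seq_len(n_mod)) {
      p <- match(mod_path[i], names(sets))
      intr[i, ] <- coupling[i] * modulator_weight * path_mean_z[, p] +
        noise_sd * intr[i, ]
    }
  }
  lnc <- intr + purity_weight *
    matrix(pur_z, n_lnc, n_samples, byrow = TRUE) + mu_l

  age <- stats::rnorm(n_samples, 60, 10)
  # hazards act on the tumor-intrinsic lncRNA component: bulk purity is a
  # composition artifact and must not make every lncRNA prognostic
  eta <- age_beta * (age - 60)
  for (id in prog_ids) eta <- eta + betas[[id]] * as.numeric(scale(intr[id, ]))
  h0 <- log(2) / baseline_median
  t_event <- stats::rexp(n_samples) / (h0 * exp(eta))

  if (censor_rate == 0) {
    time <- t_event
    event <- rep(1, n_samples)
  } else {
    # uniform censoring C ~ U(0, tau); E[censored] = mean(min(T/tau, 1))
    # is monotone decreasing in tau, solve for the requested rate
    f <- function(tau) mean(pmin(t_event / tau, 1)) - censor_rate
    hi <- max(t_event) / censor_rate * 2
    tau <- stats::uniroot(f, c(min(t_event) * 1e-6, hi))$root
    cens <- stats::runif(n_samples, 0, tau)
    event <- as.numeric(t_event <= cens)
    time <- pmin(t_event, cens)
  }

  surv <- data.frame(sample = samples, time = time, event = event, age = age,
                     stringsAsFactors = FALSE)
  truth <- list(
    subtype = subtype,
    modulator_pairs = data.frame(lnc_id = mod_ids, pathway = mod_path,
                                 stringsAsFactors = FALSE),
    prognostic_lnc = betas,
    purity = purity,
    seed = as.integer(seed)
  )
  class(truth) <- "cohort_truth"
  list(mrna = mrna, lnc = lnc, surv = surv, truth = truth)
}

#' Simulate multiple cohorts sharing planted truth structure
#'
#' Cohorts share the planted modulator pairs and the signs/magnitudes of the
#' prognostic log-hazards (the layout is deterministic in the generator
#' arguments), but differ in sample draws, gene-level batch offsets with SD
#' `batch_sd` (applied to both feature spaces) and independent noise.
#'
#' @param gene_sets A `gene_set_collection`.
#' @param n_cohorts Number of cohorts (>= 2).
#' @param n_samples Integer vector of cohort sizes (recycled to
#'   `n_cohorts`).
#' @param batch_sd SD of per-gene additive batch offsets.
#' @param seeds Integer vector of length `n_cohorts`.
#' @param cohort_ids Optional character vector of cohort id prefixes.
#' @param ... Further arguments passed to [generate_cohort()].
#' @return List of cohort lists as returned by [generate_cohort()].
#' @export
generate_multi_cohorts <- function(gene_sets, n_cohorts = 4,
                                   n_samples = c(350, 100, 64, 68),
                                   batch_sd = 0.5, seeds = NULL,
                                   cohort_ids = NULL, ...) {
  if (n_cohorts < 2) stop("n_cohorts must be >= 2")
  if (is.null(seeds)) stop("`seeds` must be supplied")
  if (length(seeds) != n_cohorts)
    stop("`seeds` must have length n_cohorts")
  if (batch_sd < 0) stop("batch_sd must be >= 0")
  n_samples <- rep_len(n_samples, n_cohorts)
  if (is.null(cohort_ids)) cohort_ids <- sprintf("C%d", seq_len(n_cohorts))
  lapply(seq_len(n_cohorts), function(i) {
    co <- generate_cohort(gene_sets, n_samples = n_samples[i],
                          seed = seeds[i], cohort_id = cohort_ids[i], ...)
    if (batch_sd > 0) {
      off_m <- .with_seed(.key_seed(seeds[i], paste0("batch_m", i)),
                          stats::rnorm(nrow(co$mrna), 0, batch_sd))
      off_l <- .with_seed(.key_seed(seeds[i], paste0("batch_l", i)),
                          stats::rnorm(nrow(co$lnc), 0, batch_sd))
      co$mrna <- co$mrna + off_m
      co$lnc <- co$lnc + off_l
    }
    co
  })
}
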