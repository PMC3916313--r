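#' Beta to M-value (base-2 logit) transform
#'
#' `M = log2(beta' / (1 - beta'))` with `beta'` clamped to
#' `[clip, 1 - clip]`. The clip keeps M-values finite for fully
#' (un)methylated probes; at the default `clip = 0.001` the M-value range
#' is roughly plus or minus 10.
#'
#' @param beta A [beta_matrix()].
#' @param clip Clamp bound, in `(0, 0.5)`.
#' @return An [mvalue_matrix()] with the same axes and annotation.
#' @export
logit_transform <- function(beta, clip = 0.001) {
  stopifnot(clip > 0, clip < 0.5)
  b <- pmin(pmax(beta$values, clip), 1 - clip)
  mvalue_matrix(log2(b / (1 - b)), probes = beta$probes)
}

#' M-value to beta (inverse base-2 logit)
#'
#' `beta = 2^M / (1 + 2^M)`; exact inverse of [logit_transform()] away
#' from the clip bounds.
#'
#' @param M An [mvalue_matrix()].
#' @return A [beta_matrix()].
#' @export
inverse_logit <- function(M) {
  e <- 2^M$values
  beta_matrix(e / (1 + e), probes = M$probes)
}

#' Probe-level quality filters
#'
#' Removes probes in a fixed order so the reported exclusion reason is the
#' first failing rule: (1) rsid-named probes, (2) Y-chromosome probes,
#' (3) probes overlapping a SNP, (4) probes whose bisulfite negative
#' control beta exceeds the mean plus four standard deviations of all
#' probes' negative-control betas, (5) probes detected (detection
#' p <= `detection_alpha`) in fewer than `min_detected` of samples.
#'
#' @param beta A [beta_matrix()] with a detection p-value layer.
#' @param negative_control_beta Optional named vector of negative-control
#'   beta values, one per probe; when `NULL` the negative-control rule is
#'   skipped.
#' @param detection_alpha Detection p-value cut-off (default 0.05).
#' @param min_detected Minimum fraction of samples in which a probe must
#'   be detected (default 0.70; strictly-less fails).
#' @param nc_sd_mult Multiplier on the negative-control SD (default 4).
#' @return A list with the filtered `beta` and a `report` tibble of
#'   excluded probes and reasons.
#' @export
filter_probes <- function(beta, negative_control_beta = NULL,
                          detection_alpha = 0.05, min_detected = 0.70,
                          nc_sd_mult = 4) {
  if (is.null(beta$detection_p)) {
    abort("`beta` has no detection p-value layer; filter_probes needs one.")
  }
  ids <- rownames(beta$values)
  ann <- beta$probes
  reason <- rep(NA_character_, length(ids))

  flag <- function(cond, label) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- label
  }
  flag(ann$is_rsid_named, "rsid_named")
  flag(!is.na(ann$chr) & ann$chr %in% c("Y", "chrY"), "y_chromosome")
  flag(ann$overlaps_snp, "snp_overlap")
  if (!is.null(negative_control_beta)) {
    nc <- negative_control_beta[ids]
    thr <- mean(negative_control_beta, na.rm = TRUE) +
      nc_sd_mult * sd(negative_control_beta, na.rm = TRUE)
    flag(!is.na(nc) & nc > thr, "negative_control_high")
  }
  # an NA detection p counts as not detected
  detected <- rowMeans(!is.na(beta$detection_p) &
                         beta$detection_p <= detection_alpha)
  flag(detected < min_detected, "low_detection")

  keep <- is.na(reason)
  report <- tibble::tibble(id = ids[!keep], reason = reason[!keep],
                           kind = "probe")
  out <- beta_matrix(beta$values[keep, , drop = FALSE],
                     probes = ann[keep, , drop = FALSE],
                     detection_p = beta$detection_p[keep, , drop = FALSE])
  list(beta = out, report = report)
}

#' Sample-level quality filter
#'
#' Excludes a sample when strictly more than `max_failed` of its probes
#' have detection p-values exceeding `detection_threshold`.
#'
#' @param beta A [beta_matrix()] with a detection p-value layer.
#' @param detection_threshold Detection p-value above which a probe counts
#'   as failed for the sample (default `1e-5`).
#' @param max_failed Maximum tolerated failed-probe fraction (default
#'   0.25; a sample at exactly 0.25 is retained).
#' @return A list with the filtered `beta` and a `report` tibble.
#' @export
filter_samples <- function(beta, detection_threshold = 1e-5,
                           max_failed = 0.25) {
  if (is.null(beta$detection_p)) {
    abort("`beta` has no detection p-value layer; filter_samples needs one.")
  }
  failed <- colMeans(beta$detection_p > detection_threshold, na.rm = TRUE)
  keep <- failed <= max_failed
  report <- tibble::tibble(id = colnames(beta$values)[!keep],
                           reason = "high_detection_failure", kind = "sample")
  out <- beta_matrix(beta$values[, keep, drop = FALSE],
                     probes = beta$probes,
                     detection_p = beta$detection_p[, keep, drop = FALSE])
  list(beta = out, report = report)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the binomial expectation at the observed allele frequency.
#' A monomorphic SNP returns `p = 1` by convention.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total >= 1).
#' @return The p-value, with the chi-square statistic as attribute
#'   `"statistic"`.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  stopifnot(n >= 1)
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) {
    return(structure(1, statistic = 0))
  }
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(n_AA, n_Aa, n_aa) - expected)^2 / expected)
  structure(pchisq(chi2, df = 1, lower.tail = FALSE), statistic = chi2)
}

#' SNP-level quality filters
#'
#' Applies, in order: call rate < `min_call_rate` (strict), minor allele
#' frequency < `min_maf` (strict, computed on non-missing dosages), and
#' Hardy-Weinberg p-value < `hwe_alpha`. The reported reason is the first
#' failing rule.
#'
#' @param geno A [genotype_matrix()].
#' @param min_call_rate Minimum call rate (default 0.95).
#' @param min_maf Minimum minor allele frequency (default 0.05).
#' @param hwe_alpha HWE p-value threshold (default `1e-4`).
#' @return A list with the filtered `geno` and a `report` tibble.
#' @export
filter_snps <- function(geno, min_call_rate = 0.95, min_maf = 0.05,
                        hwe_alpha = 1e-4) {
  d <- geno$dosages
  call_rate <- colMeans(!is.na(d))
  freq <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    g <- d[!is.na(d[, j]), j]
    if (length(g) == 0) return(1)
    as.numeric(hwe_test(sum(g == 0), sum(g == 1), sum(g == 2)))
  }, numeric(1))

  reason <- rep(NA_character_, ncol(d))
  reason[call_rate < min_call_rate] <- "call_rate"
  reason[is.na(reason) & maf < min_maf] <- "maf"
  reason[is.na(reason) & hwe_p < hwe_alpha] <- "hwe"
  keep <- is.na(reason)
  report <- tibble::tibble(id = colnames(d)[!keep], reason = reason[!keep],
                           kind = "snp")
  out <- genotype_matrix(d[, keep, drop = FALSE],
                         snps = geno$snps[keep, , drop = FALSE])
  list(geno = out, report = report)
}

#' Principal-component diagnostics for batch and plate effects
#'
#' PCA on probe-centred M-values (samples as observations, no variance
#' scaling), components ordered by decreasing explained variance; each of
#' the top components is tested for association with batch and plate by
#' one-way ANOVA on its scores.
#'
#' @param M An [mvalue_matrix()].
#' @param samples Sample table with `sample_id` and (optionally) `batch`
#'   and `plate` columns.
#' @param n_components Number of leading components to report.
#' @return A list with `scores` (tibble, sample x component), and
#'   `summary` (tibble: component, variance fraction, ANOVA p-values for
#'   batch and plate where available).
#' @export
pca_diagnostics <- function(M, samples, n_components = 5) {
  samples <- validate_sample_table(samples)
  x <- t(M$values[, samples$sample_id, drop = FALSE])
  if (all(apply(x, 2, var) < .Machine$double.eps)) {
    abort("matrix is constant; no variance to decompose.")
  }
  n_components <- min(n_components, nrow(x) - 1L, ncol(x))
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x[, seq_len(n_components), drop = FALSE])
  scores <- dplyr::bind_cols(tibble::tibble(sample_id = samples$sample_id),
                             scores)
  anova_p <- function(score, groups) {
    if (is.null(groups) || length(unique(groups)) < 2) return(NA_real_)
    summary(aov(score ~ factor(groups)))[[1]][["Pr(>F)"]][1]
  }
  summary <- tibble::tibble(
    component = paste0("PC", seq_len(n_components)),
    variance_fraction = var_frac[seq_len(n_components)],
    p_batch = vapply(seq_len(n_components), function(i) {
      anova_p(pc$x[, i], samples$batch)
    }, numeric(1)),
    p_plate = vapply(seq_len(n_components), function(i) {
      anova_p(pc$x[, i], samples$plate)
    }, numeric(1))
  )
  list(scores = scores, summary = summary)
}

#' Empirical-Bayes batch adjustment (location and scale)
#'
#' Removes per-probe batch mean and variance effects by parametric
#' empirical Bayes (ComBat), shrinking per-batch location and scale
#' estimates toward common priors. Covariates named in `protect` (e.g.
#' case status) are retained in the standardisation model so their signal
#' is not absorbed into the batch correction.
#'
#' @param M An [mvalue_matrix()].
#' @param samples Sample table with `sample_id` and `batch` columns.
#' @param protect Character vector of covariate columns to protect
#'   (default `"case_status"`).
#' @return The adjusted [mvalue_matrix()].
#' @export
combat_adjust <- function(M, samples, protect = "case_status") {
  samples <- validate_sample_table(samples)
  if (!"batch" %in% names(samples)) abort("sample table needs a `batch` column.")
  batch <- factor(samples$batch)
  if (nlevels(batch) < 2) abort("combat_adjust needs at least 2 batches.")
  if (any(table(batch) < 2)) {
    abort("every batch needs at least 2 samples (scale not estimable).")
  }
  x <- M$values[, samples$sample_id, drop = FALSE]
  mod <- NULL
  protect <- intersect(protect, names(samples))
  if (length(protect) > 0) {
    fml <- stats::as.formula(paste("~", paste(protect, collapse = "+")))
    mod <- model.matrix(fml, data = samples)
  }
  adj <- suppressMessages(sva::ComBat(dat = x, batch = batch, mod = mod,
                                      par.prior = TRUE, prior.plots = FALSE))
  mvalue_matrix(adj, probes = M$probes)
}

#' Remove plate effects by fixed-effect residualisation
#'
#' Per probe, fits an OLS model of M-values on a plate indicator and
#' returns the probe's grand mean plus the unstandardised residuals, so
#' every plate's mean is equalised while the probe grand mean is
#' preserved exactly. A singleton plate contributes a zero residual (its
#' sample is set to the grand mean).
#'
#' @param M An [mvalue_matrix()].
#' @param samples Sample table with `sample_id` and `plate` columns.
#' @return The residualised [mvalue_matrix()].
#' @export
plate_residualize <- function(M, samples) {
  samples <- validate_sample_table(samples)
  if (!"plate" %in% names(samples)) abort("sample table needs a `plate` column.")
  plate <- factor(samples$plate)
  if (nlevels(plate) < 2) abort("plate_residualize needs at least 2 plates.")
  x <- M$values[, samples$sample_id, drop = FALSE]
  grand <- rowMeans(x)
  # OLS on a plate indicator fits each plate's mean; vectorised over probes
  plate_means <- t(apply(x, 1, function(row) tapply(row, plate, mean)))
  fitted <- plate_means[, as.integer(plate), drop = FALSE]
  out <- x - fitted + grand
  mvalue_matrix(out, probes = M$probes)
}
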