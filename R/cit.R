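#' Composite CIT p-value (intersection-union)
#'
#' The causal-inference-test p-value is the maximum of the component
#' p-values of the first three conditions (G-Y association; G-M given Y;
#' M-Y given G). Vectorised over trios.
#'
#' @param p1,p2,p3 Component p-values.
#' @return `pmax(p1, p2, p3)`.
#' @export
cit_composite_p <- function(p1, p2, p3) {
  pmax(p1, p2, p3)
}

#' Cascade thresholds and options
#'
#' Default thresholds of the three-step filter and the CIT: EWAS FDR
#' q < 0.05, meQTL FDR q < 0.10, SNP-disease p < 0.05, CIT p < 0.05, and
#' condition-4 p > 0.05 (strictly greater retains the mediated label).
#'
#' @param alpha_ewas_q,alpha_meqtl_q,alpha_snp_p,alpha_cit,alpha_p4
#'   Thresholds, each in (0, 1).
#' @param cit_covariates Covariate columns entered into the four CIT
#'   regressions (default none: the conditional models contain only g, m
#'   and y).
#' @param k_probes Number of discriminating probes for deconvolution.
#' @return An object of class `cascade_config` (a named list).
#' @export
cascade_config <- function(alpha_ewas_q = 0.05, alpha_meqtl_q = 0.10,
                           alpha_snp_p = 0.05, alpha_cit = 0.05,
                           alpha_p4 = 0.05, cit_covariates = character(0),
                           k_probes = 100) {
  thr <- c(alpha_ewas_q, alpha_meqtl_q, alpha_snp_p, alpha_cit, alpha_p4)
  if (any(thr <= 0 | thr >= 1)) {
    abort("every threshold must lie strictly within (0, 1).")
  }
  structure(as.list(environment())[c("alpha_ewas_q", "alpha_meqtl_q",
                                     "alpha_snp_p", "alpha_cit", "alpha_p4",
                                     "cit_covariates", "k_probes")],
            class = "cascade_config")
}

#' Causal Inference Test for one CpG-SNP-phenotype trio
#'
#' Tests the four CIT conditions for genotype dosage `g`, methylation
#' M-value `m` and binary outcome `y`:
#' 1. G and Y are associated (logistic `y ~ g`);
#' 2. G is associated with M given Y (linear `m ~ g + y`);
#' 3. M is associated with Y given G (logistic `y ~ m + g`, p on m);
#' 4. G is independent of Y given M (logistic `y ~ g + m`, p on g).
#'
#' The composite CIT p-value is the maximum of the first three; the trio
#' is labelled `mediated` when the composite p is below `alpha_cit` and
#' the condition-4 p is strictly above `alpha_p4` (attenuation of the
#' direct G-Y association once M is conditioned on). The G-Y log-odds per
#' allele before and after conditioning on M are returned so attenuation
#' can be inspected. Wald p-values, with a likelihood-ratio fallback and
#' a flag under (quasi-)separation.
#'
#' @param g Minor-allele dosage vector.
#' @param m M-value vector.
#' @param y Binary outcome vector (0/1).
#' @param covariates Optional data frame of additional covariates entered
#'   into every conditional model.
#' @param alpha_cit,alpha_p4 Classification thresholds (defaults 0.05).
#' @param cpg_id,snp_id Optional ids carried into the result.
#' @param min_complete Minimum complete-case count (default 20).
#' @return A one-row tibble of class `trio_result`: ids, `p1`-`p4`,
#'   `p_cit`, `label`, `g_y_coef_unadjusted`, `g_y_coef_m_adjusted`,
#'   `separation_flag`.
#' @export
cit_test <- function(g, m, y, covariates = NULL,
                     alpha_cit = 0.05, alpha_p4 = 0.05,
                     cpg_id = NA_character_, snp_id = NA_character_,
                     min_complete = 20) {
  dat <- data.frame(g = g, m = m, y = y)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < min_complete) {
    abort(sprintf("only %d complete cases (< %d).", nrow(dat), min_complete))
  }
  if (var(dat$g) < .Machine$double.eps) abort("`g` is constant.")
  if (var(dat$m) < .Machine$double.eps) abort("`m` is constant.")
  if (length(unique(dat$y)) < 2) abort("`y` must contain both classes.")

  base <- setdiff(names(dat), c("g", "m", "y"))
  sub <- function(cols) dat[, cols, drop = FALSE]

  f1 <- logistic_fit(y ~ ., sub(c("y", "g", base)), "g")
  lm2 <- lm(m ~ ., data = sub(c("m", "g", "y", base)))
  sm2 <- summary(lm2)$coefficients
  p2 <- sm2["g", 4]
  f34 <- sub(c("y", "m", "g", base))
  f3 <- logistic_fit(y ~ ., f34, "m")
  f4 <- logistic_fit(y ~ ., f34, "g")

  p1 <- f1$p_value
  p3 <- f3$p_value
  p4 <- f4$p_value
  p_cit <- cit_composite_p(p1, p2, p3)
  label <- if (p_cit < alpha_cit && p4 > alpha_p4) "mediated" else "not_mediated"

  out <- tibble::tibble(
    cpg_id = cpg_id, snp_id = snp_id,
    p1 = p1, p2 = p2, p3 = p3, p4 = p4, p_cit = p_cit, label = label,
    g_y_coef_unadjusted = f1$estimate,
    g_y_coef_m_adjusted = f4$estimate,
    separation_flag = f1$separation || f3$separation || f4$separation
  )
  class(out) <- c("trio_result", class(out))
  out
}

#' Classify trios and summarise the mediated pair list
#'
#' Re-applies the mediation rule (`p_cit < alpha_cit` and `p4 >
#' alpha_p4`) to a table of trio results and reports the mediated pairs
#' together with unique-CpG and unique-SNP counts. Rows with a missing
#' `p4` (e.g. a published mediated list that does not print the
#' condition-4 p-value because it already passed that screen) are treated
#' as having passed the screen, with a message.
#'
#' @param trios A tibble with at least `cpg_id`, `snp_id`, `p1`, `p2`,
#'   `p3` and optionally `p4` (rows from [cit_test()] or a published
#'   table mapped onto the same columns).
#' @param cfg A [cascade_config()].
#' @return A list with `pairs` (the mediated rows), `n_pairs`, `n_cpgs`,
#'   `n_snps`.
#' @export
classify_pairs <- function(trios, cfg = cascade_config()) {
  trios <- tibble::as_tibble(trios)
  if (nrow(trios) == 0) {
    return(list(pairs = trios, n_pairs = 0L, n_cpgs = 0L, n_snps = 0L))
  }
  p_cit <- cit_composite_p(trios$p1, trios$p2, trios$p3)
  p4 <- if ("p4" %in% names(trios)) trios$p4 else rep(NA_real_, nrow(trios))
  if (anyNA(p4)) {
    inform("rows with missing p4 are treated as having passed the condition-4 screen")
  }
  pass4 <- is.na(p4) | p4 > cfg$alpha_p4
  mediated <- p_cit < cfg$alpha_cit & pass4
  pairs <- trios[mediated, , drop = FALSE]
  pairs$p_cit <- p_cit[mediated]
  list(
    pairs = pairs,
    n_pairs = nrow(pairs),
    n_cpgs = length(unique(pairs$cpg_id)),
    n_snps = length(unique(pairs$snp_id))
  )
}

#' Published mediated CpG-SNP pairs
#'
#' The mediated pair list reported by a published blood-methylation
#' case-control study of epithelial ovarian cancer (Illumina 27K, n =
#' 428): 17 CpG-SNP pairs with the component p-values of the CIT. Used
#' in examples and as a worked check of the composite-p rule.
#'
#' Columns: `cpg_id`, `meth_diff` (beta-scale case-control difference),
#' `p_m_y` (condition 3, methylation vs outcome), `gene`, `cpg_chr`,
#' `cpg_pos`, `snp_id`, `snp_chr`, `snp_pos`, `p_g_m` (condition 2,
#' genotype vs methylation), `p_g_y` (condition 1, genotype vs outcome),
#' `p_cit` (printed composite).
#'
#' @return A tibble with 17 rows.
#' @export
published_mediators <- function() {
  path <- system.file("extdata", "published_mediated_pairs.tsv",
                      package = "citewas")
  readr::read_tsv(path, show_col_types = FALSE)
}
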