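# Vectorised OLS of a response matrix on one design: returns estimate, se,
# t and p for a single named coefficient, one row per response column.
ols_matrix <- function(Y, X, coef_name) {
  qrX <- qr(X)
  rank <- qrX$rank
  if (rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(rank + 1):ncol(X)]]
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  co <- qr.coef(qrX, Y)
  res <- Y - X %*% co
  df <- nrow(X) - rank
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrX))
  j <- match(coef_name, colnames(X))
  se <- sqrt(sigma2 * xtx_inv[j, j])
  est <- co[j, ]
  stat <- est / se
  tibble::tibble(
    estimate = unname(est), se = unname(se), statistic = unname(stat),
    p_value = unname(2 * pt(abs(stat), df = df, lower.tail = FALSE))
  )
}

# Standard covariate block used by the cell-adjusted EWAS.
EWAS_COVARIATES <- c("age", "smoking", "alcohol", "enrollment_year",
                     "residence", "parity", "ancestry_pc1")

#' Cell-adjusted epigenome-wide association study
#'
#' Per CpG, OLS of the M-value on case status, the six estimated
#' leukocyte fractions, and the epidemiological covariates (age, smoking,
#' alcohol, enrollment-year stratum, residence, parity stratum, ancestry
#' PC1). The reported effect is the case-status coefficient (M-value
#' difference, cases minus controls) with a two-sided t p-value and a
#' Storey q-value.
#'
#' If the design is collinear because the six fractions sum to ~1, the
#' smallest-variance fraction is dropped automatically (with a message);
#' any other collinearity is an error naming the offending columns.
#'
#' @param M An [mvalue_matrix()].
#' @param samples Sample table; must contain `case_status` and the
#'   covariates in `covariates`.
#' @param props A `cell_proportions` tibble from [estimate_proportions()],
#'   or `NULL` for an unadjusted model.
#' @param covariates Covariate columns to adjust for; defaults to the
#'   standard set, intersected with what the table provides.
#' @return A tibble of class `ewas_result`: `probe_id`, `estimate`, `se`,
#'   `statistic`, `p_value`, `q_value`.
#' @export
ewas <- function(M, samples, props = NULL,
                 covariates = EWAS_COVARIATES) {
  samples <- validate_sample_table(samples)
  ids <- samples$sample_id
  Y <- t(M$values[, ids, drop = FALSE])

  keep <- apply(Y, 2, function(col) var(col) > .Machine$double.eps)
  if (!all(keep)) {
    warn(sprintf("dropping %d constant CpG(s) from the EWAS", sum(!keep)))
    Y <- Y[, keep, drop = FALSE]
  }

  covariates <- intersect(covariates, names(samples))
  dat <- samples[, c("case_status", covariates), drop = FALSE]
  cell_cols <- character(0)
  if (!is.null(props)) {
    p <- tibble::as_tibble(props)[match(ids, props$sample_id), CELL_TYPES]
    dat <- dplyr::bind_cols(dat, p)
    cell_cols <- CELL_TYPES
  }
  fml <- stats::as.formula(paste("~", paste(names(dat), collapse = "+")))
  X <- model.matrix(fml, data = dat)

  if (qr(X)$rank < ncol(X) && length(cell_cols) > 0) {
    vars <- vapply(cell_cols, function(ct) var(dat[[ct]]), numeric(1))
    drop_ct <- names(which.min(vars))
    inform(paste0("cell fractions are collinear; dropping `", drop_ct, "`"))
    dat[[drop_ct]] <- NULL
    fml <- stats::as.formula(paste("~", paste(names(dat), collapse = "+")))
    X <- model.matrix(fml, data = dat)
  }

  res <- ols_matrix(Y, X, "case_status")
  res <- dplyr::bind_cols(tibble::tibble(probe_id = colnames(Y)), res)
  res$q_value <- fdr_qvalues(res$p_value)
  class(res) <- c("ewas_result", class(res))
  res
}

#' Methylation-QTL scan under an additive minor-allele dosage model
#'
#' Per CpG-SNP pair, the OLS slope of the M-value on minor-allele dosage
#' (no covariates), with a two-sided t p-value. q-values are computed over
#' all tested pairs jointly. SNPs monomorphic in the analysed samples are
#' skipped with a message.
#'
#' @param M An [mvalue_matrix()], typically restricted to
#'   EWAS-significant CpGs.
#' @param geno A [genotype_matrix()].
#' @param min_complete Minimum pairwise-complete sample count (default 10).
#' @return A tibble of class `meqtl_result`: `probe_id`, `snp_id`,
#'   `estimate` (M-value per allele), `se`, `statistic`, `p_value`,
#'   `q_value`.
#' @export
meqtl_scan <- function(M, geno, min_complete = 10) {
  shared <- intersect(colnames(M$values), rownames(geno$dosages))
  if (nrow(M$values) < 1 || ncol(geno$dosages) < 1) {
    abort("need at least one CpG and one SNP.")
  }
  Mm <- M$values[, shared, drop = FALSE]
  D <- geno$dosages[shared, , drop = FALSE]
  out <- vector("list", ncol(D))
  skipped <- 0L
  for (j in seq_len(ncol(D))) {
    g <- D[, j]
    ok <- !is.na(g)
    if (sum(ok) < min_complete || var(g[ok]) < .Machine$double.eps) {
      skipped <- skipped + 1L
      next
    }
    X <- cbind(`(Intercept)` = 1, dosage = g[ok])
    res <- ols_matrix(t(Mm[, ok, drop = FALSE]), X, "dosage")
    out[[j]] <- dplyr::bind_cols(
      tibble::tibble(probe_id = rownames(Mm), snp_id = colnames(D)[j]), res)
  }
  if (skipped > 0) {
    inform(sprintf("skipped %d monomorphic/under-covered SNP(s)", skipped))
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) > 0) res$q_value <- fdr_qvalues(res$p_value)
  class(res) <- c("meqtl_result", class(res))
  res
}

#' SNP-disease association by additive logistic regression
#'
#' Per SNP, logistic regression of case status on minor-allele dosage
#' (crude model by default), Wald p-value; under quasi-separation the
#' p-value falls back to a likelihood-ratio test and the SNP is flagged.
#'
#' @param geno A [genotype_matrix()], typically restricted to meQTL SNPs.
#' @param samples Sample table.
#' @param covariates Optional covariate columns to adjust for (default
#'   none, a crude dosage-only model).
#' @return A tibble of class `snp_assoc_result`: `snp_id`, `estimate`
#'   (log-odds per allele), `se`, `statistic`, `p_value`, `q_value`,
#'   `separation_flag`.
#' @export
snp_disease_assoc <- function(geno, samples, covariates = character(0)) {
  samples <- validate_sample_table(samples)
  shared <- intersect(samples$sample_id, rownames(geno$dosages))
  samples <- samples[match(shared, samples$sample_id), , drop = FALSE]
  if (length(unique(samples$case_status)) < 2) {
    abort("both outcome groups must be non-empty.")
  }
  D <- geno$dosages[shared, , drop = FALSE]
  rows <- purrr::map_dfr(seq_len(ncol(D)), function(j) {
    dat <- data.frame(y = samples$case_status, dosage = D[, j],
                      samples[, covariates, drop = FALSE])
    dat <- dat[complete.cases(dat), , drop = FALSE]
    fit <- logistic_fit(y ~ ., dat, "dosage")
    tibble::tibble(snp_id = colnames(D)[j], estimate = fit$estimate,
                   se = fit$se, statistic = fit$statistic,
                   p_value = fit$p_value, separation_flag = fit$separation)
  })
  rows$q_value <- fdr_qvalues(rows$p_value)
  rows <- rows[, c("snp_id", "estimate", "se", "statistic", "p_value",
                   "q_value", "separation_flag")]
  class(rows) <- c("snp_assoc_result", class(rows))
  rows
}

# Logistic fit returning Wald statistics for `term`, with a
# likelihood-ratio fallback when the fit shows (quasi-)separation.
logistic_fit <- function(formula, data, term) {
  w <- FALSE
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial()),
    warning = function(cond) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(cond)) ||
          grepl("algorithm did not converge", conditionMessage(cond))) {
        w <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  sm <- summary(fit)$coefficients
  if (!term %in% rownames(sm)) {
    return(list(estimate = NA_real_, se = NA_real_, statistic = NA_real_,
                p_value = NA_real_, separation = TRUE))
  }
  est <- sm[term, 1]; se <- sm[term, 2]
  stat <- sm[term, 3]; p <- sm[term, 4]
  separation <- w || abs(est) > 15
  if (separation) {
    # likelihood-ratio fallback: drop the term and compare deviances
    dat0 <- data
    dat0[[term]] <- NULL
    fit0 <- suppressWarnings(glm(formula, data = dat0, family = binomial()))
    lr <- fit0$deviance - fit$deviance
    p <- pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
  }
  list(estimate = est, se = se, statistic = stat, p_value = p,
       separation = separation)
}

#' Storey q-values with Benjamini-Hochberg fallback
#'
#' Estimates the null proportion pi0 by Storey's smoother over the lambda
#' grid 0.05, 0.10, ..., 0.95 and returns `q_i = pi0 * min_{p_j >= p_i}
#' (n * p_j / rank_j)`. When the smoother estimate is unstable (pi0
#' outside (0, 1], or fewer than 100 p-values), pi0 is set to 1, which
#' reduces exactly to Benjamini-Hochberg. Output order matches input.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param pi0 Optional fixed pi0 (e.g. `1` to force BH).
#' @return Numeric vector of q-values.
#' @export
fdr_qvalues <- function(p, pi0 = NULL) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must be in [0, 1] and non-missing.")
  }
  n <- length(p)
  if (is.null(pi0)) {
    pi0 <- estimate_pi0(p)
  }
  stopifnot(pi0 > 0, pi0 <= 1)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * pmin(1, cummin(n / seq(n, 1) * p[o]))[ro]
  pmin(q, 1)
}

estimate_pi0 <- function(p) {
  n <- length(p)
  if (n < 100) return(1)
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- try(smooth.spline(lambda, pi0_l, df = 3), silent = TRUE)
  if (inherits(fit, "try-error")) return(1)
  pi0 <- predict(fit, x = max(lambda))$y
  if (!is.finite(pi0) || pi0 <= 0 || pi0 > 1) return(1)
  pi0
}

#' Pairwise linkage disequilibrium as squared dosage correlation
#'
#' `r^2` is the squared Pearson correlation of dosage vectors over
#' pairwise-complete samples; the matrix is symmetric with unit diagonal.
#' SNPs monomorphic in the analysed samples get `NA` rows/columns.
#'
#' @param geno A [genotype_matrix()].
#' @param snp_ids SNP ids to include (at least 2); default all.
#' @return A symmetric numeric matrix of r-squared values.
#' @export
ld_r2 <- function(geno, snp_ids = NULL) {
  if (is.null(snp_ids)) snp_ids <- colnames(geno$dosages)
  if (length(snp_ids) < 2) abort("need at least 2 SNPs for an LD matrix.")
  D <- geno$dosages[, snp_ids, drop = FALSE]
  mono <- apply(D, 2, function(g) var(g, na.rm = TRUE) < .Machine$double.eps)
  r2 <- suppressWarnings(cor(D, use = "pairwise.complete.obs"))^2
  r2[mono, ] <- NA_real_
  r2[, mono] <- NA_real_
  diag(r2)[!mono] <- 1
  r2
}

#' Direction consistency between two association result sets
#'
#' Over the features significant in both sets at the stated thresholds,
#' the fraction whose effect estimates share a sign.
#'
#' @param setA,setB Association result tibbles with a shared feature id
#'   column (first column), `estimate`, and the column named in `by`.
#' @param alphaA,alphaB Significance thresholds applied to `by` in each
#'   set (defaults 0.05).
#' @param by Column used for the significance screen (default
#'   `"q_value"`).
#' @return The fraction in `[0, 1]`, with attribute `"n_shared"`.
#' @export
direction_consistency <- function(setA, setB, alphaA = 0.05, alphaB = 0.05,
                                  by = "q_value") {
  idA <- names(setA)[1]
  a <- setA[setA[[by]] < alphaA, c(idA, "estimate")]
  b <- setB[setB[[by]] < alphaB, c(names(setB)[1], "estimate")]
  names(a) <- c("id", "est_a")
  names(b) <- c("id", "est_b")
  m <- dplyr::inner_join(a, b, by = "id")
  if (nrow(m) == 0) abort("no shared significant features; fraction undefined.")
  structure(mean(sign(m$est_a) == sign(m$est_b)), n_shared = nrow(m))
}
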