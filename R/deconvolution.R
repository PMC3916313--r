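#' Select cell-type-discriminating probes from a reference panel
#'
#' Ranks probes by their between-cell-type dispersion (the variance of the
#' six subtype means — the numerator of the between-group F statistic;
#' the panel stores one mean per type, so there is no within-group term)
#' and returns the top `k`, balanced where possible between
#' hypermethylated markers (the discriminating type lies above the probe
#' mean) and hypomethylated markers.
#'
#' @param panel A [reference_panel()].
#' @param k Number of probes to select; must be at least 6 so the
#'   projection is determined.
#' @return Character vector of probe ids.
#' @export
select_discriminating_probes <- function(panel, k = 100) {
  if (k < 6) abort("k must be at least 6 (under-determined projection).")
  if (k > nrow(panel$means)) abort("k exceeds the panel probe count.")
  R <- panel$means
  score <- apply(R, 1, var)
  dev <- R - rowMeans(R)
  # hyper: the most extreme type is above the probe mean
  hyper <- apply(dev, 1, function(d) d[which.max(abs(d))] > 0)
  ord <- order(score, decreasing = TRUE)
  ids <- rownames(R)[ord]
  is_hyper <- hyper[ord]
  k_half <- ceiling(k / 2)
  take_hyper <- head(ids[is_hyper], k_half)
  take_hypo <- head(ids[!is_hyper], k - length(take_hyper))
  sel <- c(take_hyper, take_hypo)
  if (length(sel) < k) {
    sel <- c(sel, setdiff(ids, sel)[seq_len(k - length(sel))])
  }
  # keep panel order for determinism
  rownames(R)[sort(match(sel, rownames(R)))]
}

#' Estimate leukocyte proportions by constrained projection
#'
#' Per sample, solves the quadratic program
#' `min || beta_sample - R w ||^2` subject to `w >= 0` and `sum(w) <= 1`,
#' where `R` is the reference panel restricted to the discriminating
#' probe set. Projection is on the beta scale, where cell mixing is
#' linear in the methylated-cell fraction.
#'
#' @param beta A [beta_matrix()] (typically batch/plate-adjusted and
#'   back-transformed).
#' @param panel A [reference_panel()].
#' @param probe_set Probe ids to project on; default
#'   [select_discriminating_probes()] with `k = 100`.
#' @param renormalize If `TRUE`, rescale each sample's fractions to sum
#'   to exactly 1 for reporting (default `FALSE`).
#' @return A tibble of class `cell_proportions`: `sample_id`, the six
#'   cell-type fractions, and `fit_residual` (projection residual norm).
#' @export
estimate_proportions <- function(beta, panel, probe_set = NULL,
                                 renormalize = FALSE) {
  if (is.null(probe_set)) {
    probe_set <- select_discriminating_probes(
      panel, k = min(100, nrow(panel$means)))
  }
  probe_set <- intersect(probe_set, rownames(beta$values))
  probe_set <- intersect(probe_set, rownames(panel$means))
  if (length(probe_set) == 0) {
    abort("no probes shared between `beta` and `panel`.")
  }
  R <- panel$means[probe_set, , drop = FALSE]
  B <- beta$values[probe_set, , drop = FALSE]
  # constraints: w_i >= 0 (identity rows), sum(w) <= 1 (as -1'w >= -1)
  Amat <- cbind(diag(6), -1)
  bvec <- c(rep(0, 6), -1)
  fit_one <- function(b) {
    ok <- !is.na(b)
    Ru <- R[ok, , drop = FALSE]
    bu <- b[ok]
    D <- crossprod(Ru) + diag(1e-10, 6)
    d <- crossprod(Ru, bu)
    sol <- quadprog::solve.QP(Dmat = D, dvec = d, Amat = Amat, bvec = bvec)
    w <- pmax(sol$solution, 0)
    c(w, sqrt(sum((bu - Ru %*% w)^2)))
  }
  out <- t(apply(B, 2, fit_one))
  colnames(out) <- c(CELL_TYPES, "fit_residual")
  props <- dplyr::bind_cols(
    tibble::tibble(sample_id = colnames(B)),
    tibble::as_tibble(out)
  )
  if (renormalize) {
    s <- rowSums(props[CELL_TYPES])
    props[CELL_TYPES] <- props[CELL_TYPES] / s
  }
  class(props) <- c("cell_proportions", class(props))
  props
}

#' Compare estimated cell proportions between cases and controls
#'
#' Per cell type: difference of group means (case minus control) with a
#' Welch two-sample 95% confidence interval and p-value.
#'
#' @param props A `cell_proportions` tibble from [estimate_proportions()].
#' @param samples Sample table with `sample_id` and `case_status`.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble of class `proportion_contrast`: `cell_type`,
#'   `difference`, `conf_low`, `conf_high`, `p_value`.
#' @export
compare_proportions <- function(props, samples, conf_level = 0.95) {
  samples <- validate_sample_table(samples)
  df <- dplyr::inner_join(tibble::as_tibble(props), samples, by = "sample_id")
  if (min(table(df$case_status)) < 2) {
    abort("each outcome group needs at least 2 samples.")
  }
  rows <- purrr::map_dfr(CELL_TYPES, function(ct) {
    x <- df[[ct]][df$case_status == 1]
    y <- df[[ct]][df$case_status == 0]
    if (var(x) < 1e-20 && var(y) < 1e-20) {
      d <- mean(x) - mean(y)
      return(tibble::tibble(cell_type = ct, difference = d,
                            conf_low = d, conf_high = d,
                            p_value = if (d == 0) 1 else 0))
    }
    tt <- t.test(x, y, conf.level = conf_level)
    tibble::tibble(cell_type = ct,
                   difference = unname(tt$estimate[1] - tt$estimate[2]),
                   conf_low = tt$conf.int[1], conf_high = tt$conf.int[2],
                   p_value = tt$p.value)
  })
  class(rows) <- c("proportion_contrast", class(rows))
  rows
}

#' Variance in methylation explained by cell composition
#'
#' Per probe, the R-squared from OLS of M-values on the six estimated
#' fractions; aggregate summaries are the mean per-probe R-squared and
#' the R-squared of each top principal component regressed on the
#' fractions (systematic variability).
#'
#' @param M An [mvalue_matrix()].
#' @param props A `cell_proportions` tibble.
#' @param n_components Number of top PCs for the systematic summary.
#' @return A list with `per_probe` (tibble: probe_id, r_squared),
#'   `mean_r_squared`, and `pc_r_squared` (tibble per component).
#' @export
variance_explained <- function(M, props, n_components = 5) {
  shared <- intersect(colnames(M$values), props$sample_id)
  if (length(shared) == 0) abort("no shared samples between `M` and `props`.")
  X <- as.matrix(tibble::as_tibble(props)[match(shared, props$sample_id),
                                          CELL_TYPES])
  Y <- t(M$values[, shared, drop = FALSE])
  fit <- lm(Y ~ X)
  res <- residuals(fit)
  tss <- colSums(scale(Y, scale = FALSE)^2)
  r2 <- 1 - colSums(res^2) / tss
  r2[tss < .Machine$double.eps] <- NA_real_
  r2 <- pmin(pmax(r2, 0), 1)
  n_components <- min(n_components, length(shared) - 1L, nrow(M$values))
  pc <- prcomp(Y, center = TRUE, scale. = FALSE)
  pc_r2 <- vapply(seq_len(n_components), function(i) {
    summary(lm(pc$x[, i] ~ X))$r.squared
  }, numeric(1))
  list(
    per_probe = tibble::tibble(probe_id = rownames(M$values), r_squared = r2),
    mean_r_squared = mean(r2, na.rm = TRUE),
    pc_r_squared = tibble::tibble(component = paste0("PC", seq_len(n_components)),
                                  r_squared = pc_r2)
  )
}
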