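#' Methylation beta-value matrix
#'
#' A probe-by-sample matrix of methylation beta values (fraction of
#' methylated signal, in `[0, 1]`), with optional detection p-values of
#' identical shape and a probe annotation table.
#'
#' @param values Numeric matrix, probes in rows, samples in columns, with
#'   `rownames` = probe ids and `colnames` = sample ids. Values must lie in
#'   `[0, 1]`; `NA` is allowed.
#' @param probes Optional tibble of probe annotation with columns
#'   `probe_id`, `chr`, `pos`, `gene`, `cpg_island`, `is_rsid_named`,
#'   `overlaps_snp`. Missing columns are filled with `NA`.
#' @param detection_p Optional numeric matrix of detection p-values with
#'   the same dimensions and dimnames as `values`.
#'
#' @return An object of class `beta_matrix`: a list with elements `values`,
#'   `detection_p` and `probes`.
#' @export
beta_matrix <- function(values, probes = NULL, detection_p = NULL) {
  values <- as.matrix(values)
  check_dimnames(values, "`values` must have probe rownames and sample colnames.")
  check_unique(rownames(values), "probe id")
  check_unique(colnames(values), "sample id")
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "beta value out of [0, 1] at probe '%s', sample '%s' (value %g)",
      rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
      values[bad[1, , drop = FALSE]]
    ))
  }
  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    if (!identical(dim(detection_p), dim(values))) {
      abort("`detection_p` must have the same dimensions as `values`.")
    }
    dimnames(detection_p) <- dimnames(values)
    if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE)) {
      abort("detection p-values must lie in [0, 1].")
    }
  }
  probes <- complete_probe_annotation(probes, rownames(values))
  structure(
    list(values = values, detection_p = detection_p, probes = probes),
    class = "beta_matrix"
  )
}

#' Methylation M-value matrix
#'
#' Probe-by-sample matrix of M-values, the base-2 logit of beta values.
#' Unbounded real scale on which all linear models in the pipeline are fit.
#'
#' @param values Numeric matrix with probe rownames and sample colnames.
#' @param probes Optional probe annotation tibble (see [beta_matrix()]).
#' @return An object of class `mvalue_matrix`.
#' @export
mvalue_matrix <- function(values, probes = NULL) {
  values <- as.matrix(values)
  check_dimnames(values, "`values` must have probe rownames and sample colnames.")
  check_unique(rownames(values), "probe id")
  check_unique(colnames(values), "sample id")
  probes <- complete_probe_annotation(probes, rownames(values))
  structure(list(values = values, probes = probes), class = "mvalue_matrix")
}

#' Genotype dosage matrix
#'
#' Sample-by-SNP matrix of minor-allele dosages in `{0, 1, 2}` (`NA`
#' allowed) plus SNP annotation.
#'
#' @param dosages Numeric matrix, samples in rows, SNPs in columns, with
#'   dimnames.
#' @param snps Optional tibble with columns `snp_id`, `chr`, `pos`,
#'   `alleles`, `minor_allele`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, snps = NULL) {
  dosages <- as.matrix(dosages)
  check_dimnames(dosages, "`dosages` must have sample rownames and SNP colnames.")
  check_unique(rownames(dosages), "sample id")
  check_unique(colnames(dosages), "snp id")
  bad <- !is.na(dosages) & !(dosages %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "dosage must be 0, 1, 2 or NA; found %g at sample '%s', SNP '%s'",
      dosages[bad][1], rownames(dosages)[idx[1]], colnames(dosages)[idx[2]]
    ))
  }
  if (is.null(snps)) {
    snps <- tibble::tibble(
      snp_id = colnames(dosages), chr = NA_character_, pos = NA_integer_,
      alleles = NA_character_, minor_allele = NA_character_
    )
  } else {
    snps <- tibble::as_tibble(snps)
    if (!"snp_id" %in% names(snps)) abort("`snps` needs a `snp_id` column.")
    snps <- snps[match(colnames(dosages), snps$snp_id), , drop = FALSE]
    if (anyNA(snps$snp_id)) abort("`snps` annotation misses some SNP ids.")
  }
  structure(list(dosages = dosages, snps = snps), class = "genotype_matrix")
}

#' Leukocyte reference methylation panel
#'
#' Mean beta values of purified leukocyte subtypes (CD8 and CD4 T cells,
#' NK cells, B cells, monocytes, granulocytes) used as the target of the
#' constrained projection in [estimate_proportions()].
#'
#' @param means Numeric matrix, probes in rows, exactly the six cell types
#'   `CD8T, CD4T, NK, Bcell, Mono, Gran` in columns; values in `[0, 1]`.
#' @return An object of class `reference_panel`.
#' @export
reference_panel <- function(means) {
  means <- as.matrix(means)
  if (is.null(rownames(means))) abort("`means` must have probe rownames.")
  missing <- setdiff(CELL_TYPES, colnames(means))
  if (length(missing) > 0) {
    abort(paste0(
      "reference panel is missing cell type(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  extra <- setdiff(colnames(means), CELL_TYPES)
  if (length(extra) > 0) {
    abort(paste0("unexpected cell type column(s): ", paste(extra, collapse = ", ")))
  }
  means <- means[, CELL_TYPES, drop = FALSE]
  check_unique(rownames(means), "probe id")
  if (any(means < 0 | means > 1, na.rm = TRUE)) {
    abort("reference panel values must lie in [0, 1].")
  }
  structure(list(means = means), class = "reference_panel")
}

#' Validate a sample covariate table
#'
#' Checks the sample table contract used throughout the pipeline:
#' a `sample_id` column, a binary non-missing `case_status` (1 = case,
#' 0 = control), and uniqueness of sample ids.
#'
#' @param samples A data frame with at least `sample_id` and `case_status`.
#' @return The table as a tibble, invisibly validated.
#' @export
validate_sample_table <- function(samples) {
  samples <- tibble::as_tibble(samples)
  need <- c("sample_id", "case_status")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    abort(paste0("sample table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  check_unique(samples$sample_id, "sample id")
  y <- samples$case_status
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    abort("`case_status` must be 0/1 and non-missing for every sample.")
  }
  samples
}

complete_probe_annotation <- function(probes, probe_ids) {
  defaults <- tibble::tibble(
    probe_id = probe_ids,
    chr = NA_character_, pos = NA_integer_, gene = NA_character_,
    cpg_island = NA, is_rsid_named = NA, overlaps_snp = NA
  )
  if (is.null(probes)) {
    return(defaults)
  }
  probes <- tibble::as_tibble(probes)
  if (!"probe_id" %in% names(probes)) abort("probe annotation needs `probe_id`.")
  probes <- probes[match(probe_ids, probes$probe_id), , drop = FALSE]
  if (anyNA(probes$probe_id)) {
    abort("probe annotation misses some probes present in the matrix.")
  }
  for (col in setdiff(names(defaults), names(probes))) {
    probes[[col]] <- defaults[[col]]
  }
  probes[, union(names(defaults), names(probes))]
}

# dimnames are required only on non-empty axes: R stores NULL names on a
# zero-extent dimension, which is fine after filters drop everything
check_dimnames <- function(m, msg) {
  if ((nrow(m) > 0 && is.null(rownames(m))) ||
      (ncol(m) > 0 && is.null(colnames(m)))) {
    abort(msg)
  }
  invisible(m)
}

check_unique <- function(x, what) {
  if (anyDuplicated(x)) {
    abort(sprintf("duplicate %s: '%s'", what, x[duplicated(x)][1]))
  }
  invisible(x)
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf(
    "<beta_matrix> %d probes x %d samples%s\n",
    nrow(x$values), ncol(x$values),
    if (is.null(x$detection_p)) "" else " (with detection p-values)"
  ))
  invisible(x)
}

#' @export
print.mvalue_matrix <- function(x, ...) {
  cat(sprintf("<mvalue_matrix> %d probes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %d probes x 6 leukocyte subtypes\n",
              nrow(x$means)))
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

#' @export
dim.mvalue_matrix <- function(x) dim(x$values)

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)
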