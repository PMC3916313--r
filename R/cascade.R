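#' Run the full mediation cascade
#'
#' Executes the pipeline end to end: probe/sample/SNP quality control,
#' beta to M-value transform, empirical-Bayes batch adjustment and plate
#' residualisation (each applied only when the design has >= 2 levels),
#' leukocyte deconvolution on the adjusted, back-transformed betas,
#' cell-adjusted EWAS (keep FDR q < `alpha_ewas_q`), meQTL scan on the
#' surviving CpGs (keep q < `alpha_meqtl_q`), SNP-disease association on
#' the surviving SNPs (keep p < `alpha_snp_p`), the Causal Inference Test
#' on every surviving CpG-SNP pair, and the mediated-pair classification.
#'
#' Any stage that leaves zero survivors terminates the cascade cleanly;
#' the report still records the counts up to that stage.
#'
#' @param beta A [beta_matrix()] with detection p-values.
#' @param geno A [genotype_matrix()].
#' @param samples Sample table (see [validate_sample_table()]).
#' @param panel A [reference_panel()].
#' @param cfg A [cascade_config()].
#' @param negative_control_beta Optional per-probe negative-control betas
#'   for the probe QC rule.
#' @return A list of class `cascade_result` with elements `ewas`,
#'   `meqtl`, `snp_assoc`, `trios`, `mediated` (from [classify_pairs()]),
#'   `proportions`, `qc_report`, and `report` (tibble of stage counts).
#' @export
run_cascade <- function(beta, geno, samples, panel, cfg = cascade_config(),
                        negative_control_beta = NULL) {
  samples <- validate_sample_table(samples)
  counts <- list()
  note <- function(stage, n) counts[[length(counts) + 1]] <<-
    tibble::tibble(stage = stage, count = as.integer(n))

  note("input_probes", nrow(beta$values))
  note("input_samples", ncol(beta$values))
  note("input_snps", ncol(geno$dosages))

  # -- QC -----------------------------------------------------------------
  pq <- filter_probes(beta, negative_control_beta = negative_control_beta)
  sq <- filter_samples(pq$beta)
  beta <- sq$beta
  samples <- samples[samples$sample_id %in% colnames(beta$values), ,
                     drop = FALSE]
  gq <- filter_snps(geno)
  geno <- gq$geno
  qc_report <- dplyr::bind_rows(pq$report, sq$report, gq$report)
  note("qc_probes", nrow(beta$values))
  note("qc_samples", ncol(beta$values))
  note("qc_snps", ncol(geno$dosages))

  # -- transform and technical-effect removal -----------------------------
  M <- logit_transform(beta)
  if ("batch" %in% names(samples) && length(unique(samples$batch)) >= 2) {
    M <- combat_adjust(M, samples)
  }
  if ("plate" %in% names(samples) && length(unique(samples$plate)) >= 2) {
    M <- plate_residualize(M, samples)
  }
  beta_adj <- inverse_logit(M)

  # -- deconvolution ------------------------------------------------------
  probe_set <- select_discriminating_probes(
    panel, k = min(cfg$k_probes, nrow(panel$means)))
  props <- estimate_proportions(beta_adj, panel, probe_set = probe_set)

  # -- step 1: cell-adjusted EWAS -----------------------------------------
  ew <- ewas(M, samples, props)
  ew_keep <- ew$probe_id[ew$q_value < cfg$alpha_ewas_q]
  note("ewas_significant_cpgs", length(ew_keep))
  out <- list(ewas = ew, meqtl = NULL, snp_assoc = NULL, trios = NULL,
              mediated = list(pairs = tibble::tibble(), n_pairs = 0L,
                              n_cpgs = 0L, n_snps = 0L),
              proportions = props, qc_report = qc_report)
  finish <- function(out) {
    out$report <- dplyr::bind_rows(counts)
    structure(out, class = "cascade_result")
  }
  if (length(ew_keep) == 0) return(finish(out))

  # -- step 2: meQTL scan on survivors ------------------------------------
  M_sub <- mvalue_matrix(M$values[ew_keep, , drop = FALSE],
                         probes = M$probes[match(ew_keep, M$probes$probe_id), ])
  mq <- meqtl_scan(M_sub, geno)
  mq_keep <- mq[mq$q_value < cfg$alpha_meqtl_q, , drop = FALSE]
  note("meqtl_significant_pairs", nrow(mq_keep))
  note("meqtl_unique_snps", length(unique(mq_keep$snp_id)))
  note("meqtl_unique_cpgs", length(unique(mq_keep$probe_id)))
  out$meqtl <- mq
  if (nrow(mq_keep) == 0) return(finish(out))

  # -- step 3: SNP-disease association ------------------------------------
  snp_ids <- unique(mq_keep$snp_id)
  geno_sub <- genotype_matrix(geno$dosages[, snp_ids, drop = FALSE],
                              snps = geno$snps[match(snp_ids, geno$snps$snp_id), ])
  sa <- snp_disease_assoc(geno_sub, samples)
  sa_keep <- sa$snp_id[sa$p_value < cfg$alpha_snp_p]
  note("disease_associated_snps", length(sa_keep))
  out$snp_assoc <- sa
  pairs <- mq_keep[mq_keep$snp_id %in% sa_keep, , drop = FALSE]
  note("cit_candidate_pairs", nrow(pairs))
  if (nrow(pairs) == 0) return(finish(out))

  # -- step 4: CIT on each surviving pair ---------------------------------
  covs <- NULL
  if (length(cfg$cit_covariates) > 0) {
    covs <- samples[, intersect(cfg$cit_covariates, names(samples)),
                    drop = FALSE]
  }
  trios <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    cit_test(
      g = geno$dosages[samples$sample_id, pairs$snp_id[i]],
      m = M$values[pairs$probe_id[i], samples$sample_id],
      y = samples$case_status,
      covariates = covs,
      alpha_cit = cfg$alpha_cit, alpha_p4 = cfg$alpha_p4,
      cpg_id = pairs$probe_id[i], snp_id = pairs$snp_id[i]
    )
  })
  class(trios) <- c("trio_result", class(trios))
  out$trios <- trios
  out$mediated <- classify_pairs(trios, cfg)
  note("mediated_pairs", out$mediated$n_pairs)
  note("mediated_unique_cpgs", out$mediated$n_cpgs)
  note("mediated_unique_snps", out$mediated$n_snps)
  finish(out)
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("<cascade_result>\n")
  print(x$report, n = Inf)
  invisible(x)
}
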