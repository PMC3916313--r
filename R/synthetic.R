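#' Simulation configuration for a synthetic case-control cohort
#'
#' Collects every knob of the generator with defaults that emulate a
#' two-batch Illumina-27K-style blood-methylation case-control study of
#' 214 cases and 214 controls: cell-mixture methylation, batch and plate
#' location-scale effects, Hardy-Weinberg genotypes, and planted
#' CpG-SNP-phenotype trios of the three causal topologies (mediated
#' G -> M -> Y; consequential Y -> M; independent M <- G -> Y).
#'
#' Effects are injected on the M-value (base-2 logit) scale, the scale on
#' which every downstream model is fit:
#' * `effect_g_on_m` (a): M-value units per minor allele (mediated and
#'   independent trios);
#' * `effect_m_on_y` (b): log-odds of case status per M-value unit
#'   (mediated trios); independent trios receive a direct G -> Y log-odds
#'   of `a * b` per allele so the marginal G-Y slope matches the mediated
#'   path;
#' * `effect_y_on_m` (c): M-value shift added to case samples
#'   (consequential trios).
#'
#' @param n_cases,n_controls Sample counts. `n_cases` is a calibration
#'   target: the logistic intercept is chosen so the expected number of
#'   cases equals `n_cases`; realised counts are Bernoulli draws.
#' @param n_probes,n_snps Feature counts.
#' @param n_mediated,n_consequential,n_independent,n_null Planted trio
#'   counts per topology (`n_null` probes get a partner SNP but zero
#'   effects, useful for bookkeeping).
#' @param maf_range Minor-allele-frequency interval within (0, 0.5].
#' @param effect_g_on_m,effect_m_on_y,effect_y_on_m Effect sizes (above).
#' @param case_cell_shift Named additive shift of mixture weights applied
#'   to case samples before renormalisation. Defaults follow the
#'   qualitative case-control pattern seen in blood of ovarian-cancer
#'   patients: granulocytes up; CD4+/CD8+ T cells, and mildly B and NK
#'   cells, down.
#' @param batch_location,batch_scale Per-batch location shift (M-value
#'   units) and residual-scale multiplier; length = number of batches.
#' @param batch_prop Proportion of samples per batch.
#' @param plate_location Per-plate location shift; plates are assigned
#'   round-robin within batch.
#' @param noise_sd Residual M-value standard deviation.
#' @param detection_fail_rate Fraction of detection p-values drawn from
#'   the failing range (above 0.05); passing cells are drawn uniform on
#'   (0, 1e-6), comfortably inside both the probe-level (0.05) and
#'   sample-level (1e-5) detection rules.
#' @param dirichlet_center,dirichlet_conc Centre (must be named by cell
#'   type, summing to 1) and concentration of the Dirichlet prior for the
#'   control mixture.
#' @param seed Integer seed driving per-stage substreams.
#' @return An object of class `simulation_config` (a named list).
#' @export
simulation_config <- function(n_cases = 214, n_controls = 214,
                              n_probes = 2000, n_snps = 500,
                              n_mediated = 5, n_consequential = 5,
                              n_independent = 5, n_null = 0,
                              maf_range = c(0.05, 0.5),
                              effect_g_on_m = 0.8, effect_m_on_y = 1.0,
                              effect_y_on_m = 0.5,
                              case_cell_shift = c(CD8T = -0.02, CD4T = -0.02,
                                                  NK = -0.005, Bcell = -0.005,
                                                  Mono = 0, Gran = 0.05),
                              batch_location = c(0.5, -0.5),
                              batch_scale = c(1.1, 0.9),
                              batch_prop = c(132, 296) / 428,
                              plate_location = c(0.2, -0.2, 0.1, -0.1),
                              noise_sd = 0.5,
                              detection_fail_rate = 0.002,
                              dirichlet_center = c(CD8T = 0.10, CD4T = 0.15,
                                                   NK = 0.05, Bcell = 0.06,
                                                   Mono = 0.04, Gran = 0.60),
                              dirichlet_conc = 150,
                              seed = 1L) {
  cfg <- as.list(environment())
  n_planted <- n_mediated + n_consequential + n_independent + n_null
  stopifnot(
    n_cases >= 0, n_controls >= 0, n_probes > 0, n_snps > 0,
    n_mediated >= 0, n_consequential >= 0, n_independent >= 0, n_null >= 0,
    n_planted <= n_probes, n_planted <= n_snps,
    maf_range[1] > 0, maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
    length(batch_location) == length(batch_scale),
    length(batch_location) == length(batch_prop),
    abs(sum(dirichlet_center) - 1) < 1e-8
  )
  stopifnot(setequal(names(dirichlet_center), CELL_TYPES),
            setequal(names(case_cell_shift), CELL_TYPES))
  structure(cfg, class = "simulation_config")
}

# Deterministic per-stage substream below 2^31: mixes the global seed with
# a stage label so stages are independently reproducible.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483629)
}

#' Generate a synthetic leukocyte reference panel
#'
#' Each of the six cell types gets a disjoint block of
#' `n_marker_probes_per_type` marker probes whose mean beta is far from
#' the other five types (alternating hypermethylated 0.85-vs-0.15 and
#' hypomethylated 0.15-vs-0.85 markers, so discrimination is balanced).
#' Non-marker probes share one common mean across all types, drawn from a
#' bimodal distribution resembling array-wide methylation.
#'
#' @param n_probes Total probe count.
#' @param n_marker_probes_per_type Markers per cell type (6x this must
#'   fit in `n_probes`).
#' @param seed Integer seed.
#' @return A [reference_panel()]. Marker probe ids carry the pattern
#'   `cpgM<type>_<i>`; their assignment is recoverable from the ids.
#' @export
generate_reference_panel <- function(n_probes, n_marker_probes_per_type = 10,
                                     seed = 1L) {
  n_marker <- 6L * n_marker_probes_per_type
  if (n_marker > n_probes) {
    abort("6 * n_marker_probes_per_type exceeds n_probes; infeasible panel.")
  }
  set.seed(stage_seed(seed, "reference_panel"))
  means <- matrix(NA_real_, nrow = n_probes, ncol = 6,
                  dimnames = list(NULL, CELL_TYPES))
  ids <- character(n_probes)
  row <- 1L
  for (ct in CELL_TYPES) {
    for (i in seq_len(n_marker_probes_per_type)) {
      hyper <- i %% 2L == 1L
      own <- if (hyper) 0.85 else 0.15
      other <- if (hyper) 0.15 else 0.85
      means[row, ] <- other
      means[row, ct] <- own
      ids[row] <- sprintf("cpgM%s_%03d", ct, i)
      row <- row + 1L
    }
  }
  n_rest <- n_probes - n_marker
  if (n_rest > 0) {
    u <- runif(n_rest)
    common <- ifelse(u < 0.4, stats::rbeta(n_rest, 2, 10),
                     ifelse(u < 0.8, stats::rbeta(n_rest, 10, 2),
                            stats::rbeta(n_rest, 2, 2)))
    common <- pmin(pmax(common, 0.02), 0.98)
    means[(n_marker + 1L):n_probes, ] <- matrix(rep(common, 6), ncol = 6)
    ids[(n_marker + 1L):n_probes] <- sprintf("cpg%05d", seq_len(n_rest))
  }
  rownames(means) <- ids
  reference_panel(means)
}

#' Generate Hardy-Weinberg genotypes
#'
#' Independent SNPs (no linkage disequilibrium); each SNP's minor-allele
#' frequency is uniform on `maf_range` and dosages are binomial(2, p).
#'
#' @param n_samples,n_snps Dimensions.
#' @param maf_range MAF interval within (0, 0.5].
#' @param seed Integer seed.
#' @param sample_ids Optional sample ids (default `S0001...`).
#' @return A [genotype_matrix()]; true MAFs are stored in the SNP
#'   annotation column `true_maf`.
#' @export
generate_genotypes <- function(n_samples, n_snps, maf_range = c(0.05, 0.5),
                               seed = 1L, sample_ids = NULL) {
  stopifnot(n_samples >= 2)
  set.seed(stage_seed(seed, "genotypes"))
  maf <- runif(n_snps, maf_range[1], maf_range[2])
  d <- vapply(maf, function(p) rbinom(n_samples, 2L, p), numeric(n_samples))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n_samples))
  snp_ids <- sprintf("snp%05d", seq_len(n_snps))
  dimnames(d) <- list(sample_ids, snp_ids)
  genotype_matrix(d, snps = tibble::tibble(
    snp_id = snp_ids, chr = NA_character_, pos = NA_integer_,
    alleles = "A/B", minor_allele = "B", true_maf = maf
  ))
}

rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Generate a full synthetic cohort with ground truth
#'
#' Builds, in order: per-sample leukocyte mixtures from a Dirichlet prior;
#' baseline beta as the fraction-weighted mixture of the panel means;
#' M-values with additive genotype effects for mediated and independent
#' trios plus residual biological noise (`noise_sd`), which is drawn
#' before the outcome because it is variation in the mediator itself;
#' case status from a logistic model whose intercept is calibrated so
#' the expected case count equals `n_cases` (mediated trios act through
#' M, independent trios directly through G); a case shift of the mixture
#' weights (composition change as a consequence of disease, rebuilt into
#' the baseline); the consequential Y -> M shift; technical batch and
#' plate location-scale effects; back-transform to beta clipped to
#' `[0.001, 0.999]`; and detection p-values.
#'
#' @param config A [simulation_config()].
#' @param panel Optional [reference_panel()] with at least
#'   `config$n_probes` probes; generated from the config seed when `NULL`.
#' @return A list of class `synthetic_cohort` with elements `beta`
#'   ([beta_matrix()]), `geno` ([genotype_matrix()]), `samples` (tibble),
#'   `panel`, and `truth` (list of tibbles: `trios`, `cell_fractions`,
#'   `batches`, `plates`).
#' @export
generate_cohort <- function(config, panel = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  if (is.null(panel)) {
    panel <- generate_reference_panel(cfg$n_probes, seed = cfg$seed)
  }
  if (nrow(panel$means) < cfg$n_probes) {
    abort("panel has fewer probes than config$n_probes.")
  }
  R <- panel$means[seq_len(cfg$n_probes), , drop = FALSE]
  n <- cfg$n_cases + cfg$n_controls
  sample_ids <- sprintf("S%04d", seq_len(n))
  probe_ids <- rownames(R)

  # -- design: batch and plate assignment ---------------------------------
  set.seed(stage_seed(cfg$seed, "design"))
  n_batches <- length(cfg$batch_prop)
  batch_sizes <- diff(round(cumsum(c(0, cfg$batch_prop)) * n))
  batch <- rep(paste0("B", seq_len(n_batches)), times = batch_sizes)
  n_plates <- length(cfg$plate_location)
  plate <- paste0("P", (seq_len(n) - 1L) %% n_plates + 1L)

  # -- genotypes ----------------------------------------------------------
  geno <- generate_genotypes(n, cfg$n_snps, cfg$maf_range, seed = cfg$seed,
                             sample_ids = sample_ids)

  # -- cell fractions (controls' distribution; case shift applied later) --
  set.seed(stage_seed(cfg$seed, "fractions"))
  alpha <- cfg$dirichlet_conc * cfg$dirichlet_center[CELL_TYPES]
  W <- rdirichlet(n, alpha)
  colnames(W) <- CELL_TYPES
  rownames(W) <- sample_ids

  # -- planted trios ------------------------------------------------------
  n_marker <- sum(grepl("^cpgM", probe_ids))
  free_probes <- probe_ids[(n_marker + 1L):length(probe_ids)]
  topology <- c(rep("mediated", cfg$n_mediated),
                rep("consequential", cfg$n_consequential),
                rep("independent", cfg$n_independent),
                rep("null", cfg$n_null))
  n_planted <- length(topology)
  if (n_planted > length(free_probes)) {
    abort("not enough non-marker probes to plant the requested trios.")
  }
  trios <- tibble::tibble(
    probe_id = free_probes[seq_len(n_planted)],
    snp_id = colnames(geno$dosages)[seq_len(n_planted)],
    topology = topology,
    a = ifelse(topology %in% c("mediated", "independent"), cfg$effect_g_on_m, 0),
    b = ifelse(topology == "mediated", cfg$effect_m_on_y, 0),
    c = ifelse(topology == "consequential", cfg$effect_y_on_m, 0),
    g_on_y_direct = ifelse(topology == "independent",
                           cfg$effect_g_on_m * cfg$effect_m_on_y, 0)
  )

  # -- baseline M plus genotype effects -----------------------------------
  build_m <- function(W) {
    mix <- R %*% t(W)                       # probes x samples, beta scale
    mix <- pmin(pmax(mix, 0.001), 0.999)
    log2(mix / (1 - mix))
  }
  E <- matrix(0, nrow = cfg$n_probes, ncol = n,
              dimnames = list(probe_ids, sample_ids))
  for (k in seq_len(n_planted)) {
    if (trios$a[k] != 0) {
      E[trios$probe_id[k], ] <- trios$a[k] * geno$dosages[, trios$snp_id[k]]
    }
  }
  # residual biological variation is part of the mediator: it is drawn
  # before the outcome so the observed (batch-corrected) M-value is the
  # quantity that carries the mediated effect
  set.seed(stage_seed(cfg$seed, "noise"))
  eps <- matrix(rnorm(cfg$n_probes * n, sd = cfg$noise_sd),
                nrow = cfg$n_probes, dimnames = list(probe_ids, sample_ids))
  M <- build_m(W) + E + eps

  # -- outcome from the calibrated logistic model -------------------------
  set.seed(stage_seed(cfg$seed, "outcome"))
  eta <- rep(0, n)
  med <- trios[trios$topology == "mediated", ]
  for (k in seq_len(nrow(med))) {
    m_k <- M[med$probe_id[k], ]
    eta <- eta + med$b[k] * (m_k - mean(m_k))
  }
  ind <- trios[trios$topology == "independent", ]
  for (k in seq_len(nrow(ind))) {
    g_k <- geno$dosages[, ind$snp_id[k]]
    eta <- eta + ind$g_on_y_direct[k] * (g_k - mean(g_k))
  }
  target <- cfg$n_cases / n
  root <- try(uniroot(function(t0) mean(stats::plogis(t0 + eta)) - target,
                      interval = c(-30, 30), tol = 1e-10), silent = TRUE)
  if (inherits(root, "try-error")) {
    abort("could not calibrate the case-count intercept; use a larger n.")
  }
  y <- rbinom(n, 1L, stats::plogis(root$root + eta))
  if (sum(y) == 0 || sum(y) == n) {
    abort("degenerate outcome draw (all cases or all controls); use a larger n.")
  }

  # -- disease-consequential composition shift ----------------------------
  if (any(cfg$case_cell_shift != 0) && sum(y) > 0) {
    shift <- cfg$case_cell_shift[CELL_TYPES]
    W[y == 1, ] <- sweep(W[y == 1, , drop = FALSE], 2, shift, "+")
    W[W < 0.001] <- 0.001
    W <- W / rowSums(W)
    M <- build_m(W) + E + eps
  }

  # -- consequential Y -> M shift -----------------------------------------
  conseq <- trios[trios$topology == "consequential", ]
  for (k in seq_len(nrow(conseq))) {
    M[conseq$probe_id[k], ] <- M[conseq$probe_id[k], ] + conseq$c[k] * y
  }

  # -- technical batch/plate location-scale effects -----------------------
  # the batch scale multiplies each probe's residual around its grand
  # mean (the location-scale model the empirical-Bayes correction assumes)
  batch_i <- as.integer(factor(batch, levels = paste0("B", seq_len(n_batches))))
  plate_i <- as.integer(factor(plate, levels = paste0("P", seq_len(n_plates))))
  grand <- rowMeans(M)
  M <- grand + (M - grand) * rep(cfg$batch_scale[batch_i],
                                 each = cfg$n_probes)
  M <- sweep(M, 2, cfg$batch_location[batch_i] + cfg$plate_location[plate_i],
             "+")

  # -- back-transform and detection p-values ------------------------------
  beta_vals <- 2^M / (1 + 2^M)
  beta_vals <- pmin(pmax(beta_vals, 0.001), 0.999)
  set.seed(stage_seed(cfg$seed, "detection"))
  detp <- matrix(runif(cfg$n_probes * n, 0, 1e-6), nrow = cfg$n_probes)
  fail <- runif(cfg$n_probes * n) < cfg$detection_fail_rate
  detp[fail] <- runif(sum(fail), 0.06, 1)
  dimnames(beta_vals) <- dimnames(detp) <- list(probe_ids, sample_ids)

  # -- covariates (independent of outcome) --------------------------------
  set.seed(stage_seed(cfg$seed, "covariates"))
  samples <- tibble::tibble(
    sample_id = sample_ids,
    case_status = y,
    age = round(pmin(pmax(rnorm(n, 61, 11), 27), 91)),
    batch = batch,
    plate = plate,
    smoking = sample(c("yes", "no"), n, TRUE, prob = c(0.1, 0.9)),
    alcohol = sample(c("never", "former", "current"), n, TRUE,
                     prob = c(0.3, 0.2, 0.5)),
    enrollment_year = sample(paste0("E", 1:5), n, TRUE),
    residence = sample(c("MN", "other"), n, TRUE, prob = c(0.6, 0.4)),
    parity = sample(paste0("par", 1:5), n, TRUE),
    ancestry_pc1 = rnorm(n),
    match_id = NA_integer_
  )

  probes <- tibble::tibble(
    probe_id = probe_ids,
    chr = as.character(rep_len(1:22, length(probe_ids))),
    pos = seq_along(probe_ids) * 1000L,
    gene = NA_character_,
    cpg_island = FALSE, is_rsid_named = FALSE, overlaps_snp = FALSE
  )

  truth <- list(
    trios = trios,
    cell_fractions = dplyr::bind_cols(
      tibble::tibble(sample_id = sample_ids), tibble::as_tibble(W)
    ),
    batches = tibble::tibble(batch = paste0("B", seq_len(n_batches)),
                             location = cfg$batch_location,
                             scale = cfg$batch_scale),
    plates = tibble::tibble(plate = paste0("P", seq_len(n_plates)),
                            location = cfg$plate_location)
  )

  structure(
    list(
      beta = beta_matrix(beta_vals, probes = probes, detection_p = detp),
      geno = geno,
      samples = samples,
      panel = panel,
      truth = truth
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d probes x %d samples; %d SNPs; %d planted trios\n",
    nrow(x$beta$values), ncol(x$beta$values), ncol(x$geno$dosages),
    nrow(x$truth$trios)
  ))
  invisible(x)
}
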