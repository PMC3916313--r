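# Small in-code fixtures shared across test files.

# A hand-sized beta matrix with annotation and detection p-values.
make_toy_beta <- function(n_probes = 6, n_samples = 4, seed = 42) {
  set.seed(seed)
  v <- matrix(runif(n_probes * n_samples, 0.05, 0.95),
              nrow = n_probes,
              dimnames = list(sprintf("cpg%03d", seq_len(n_probes)),
                              sprintf("S%02d", seq_len(n_samples))))
  detp <- matrix(runif(n_probes * n_samples, 0, 1e-6), nrow = n_probes,
                 dimnames = dimnames(v))
  ann <- tibble::tibble(
    probe_id = rownames(v),
    chr = rep(c("1", "2"), length.out = n_probes),
    pos = seq_len(n_probes) * 100L, gene = NA_character_,
    cpg_island = FALSE, is_rsid_named = FALSE, overlaps_snp = FALSE
  )
  beta_matrix(v, probes = ann, detection_p = detp)
}

# Minimal sample table with the full covariate block.
make_toy_samples <- function(n, seed = 42, n_cases = floor(n / 2)) {
  set.seed(seed)
  tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(n)),
    case_status = rep(c(1L, 0L), c(n_cases, n - n_cases)),
    age = round(runif(n, 30, 90)),
    batch = rep(c("B1", "B2"), length.out = n),
    plate = rep(c("P1", "P2"), length.out = n),
    smoking = sample(c("yes", "no"), n, TRUE),
    alcohol = sample(c("never", "former", "current"), n, TRUE),
    enrollment_year = sample(paste0("E", 1:3), n, TRUE),
    residence = sample(c("MN", "other"), n, TRUE),
    parity = sample(paste0("par", 1:3), n, TRUE),
    ancestry_pc1 = rnorm(n)
  )
}

# Independent brute-force Benjamini-Hochberg: min over the step-up of
# n * p_(j) / j for p_(j) >= p_i, implemented by direct enumeration.
brute_bh <- function(p) {
  n <- length(p)
  vapply(seq_len(n), function(i) {
    o <- order(p)
    ranks <- match(seq_len(n), o)
    min(1, min((n * p[o] / seq_len(n))[ranks[i]:n]))
  }, numeric(1))
}
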