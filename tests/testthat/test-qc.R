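test_that("logit transform matches closed forms and inverts to 1e-12", {
  v <- matrix(c(0.5, 0.8, 0.2, 0.625), nrow = 2,
              dimnames = list(c("p1", "p2"), c("A", "B")))
  b <- beta_matrix(v)
  M <- logit_transform(b)
  expect_equal(M$values["p1", "A"], 0)
  expect_equal(M$values["p2", "A"], 2)   # log2(0.8/0.2) = log2(4)
  expect_equal(M$values["p1", "B"], -2)  # antisymmetry M(b) = -M(1-b)
  back <- inverse_logit(M)
  expect_lt(max(abs(back$values - v)), 1e-12)

  # round-trip across the clipped domain
  grid <- matrix(seq(0.001, 0.999, length.out = 200), nrow = 20,
                 dimnames = list(paste0("p", 1:20), paste0("S", 1:10)))
  rt <- inverse_logit(logit_transform(beta_matrix(grid)))
  expect_lt(max(abs(rt$values - grid)), 1e-12)
})

test_that("probe filters equal a rule-by-rule brute-force oracle on random inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 60; ns <- 20
    v <- matrix(runif(n * ns), nrow = n,
                dimnames = list(sprintf("c%03d", 1:n), sprintf("S%02d", 1:ns)))
    detp <- matrix(sample(c(runif(n * ns, 0, 1e-6), runif(n * ns, 0.06, 1)),
                          n * ns), nrow = n, dimnames = dimnames(v))
    ann <- tibble::tibble(
      probe_id = rownames(v),
      chr = sample(c("1", "Y"), n, TRUE, prob = c(0.9, 0.1)),
      pos = 1:n, gene = NA_character_, cpg_island = FALSE,
      is_rsid_named = runif(n) < 0.1, overlaps_snp = runif(n) < 0.1
    )
    nc <- setNames(c(runif(n - 3), runif(3, 5, 10) * 0.1 + 0.9), rownames(v))
    b <- beta_matrix(v, probes = ann, detection_p = detp)
    got <- filter_probes(b, negative_control_beta = nc)

    # independent oracle: apply the five rules one by one
    thr <- mean(nc) + 4 * sd(nc)
    oracle <- character(0)
    for (i in 1:n) {
      id <- rownames(v)[i]
      r <- if (ann$is_rsid_named[i]) "rsid_named"
        else if (ann$chr[i] == "Y") "y_chromosome"
        else if (ann$overlaps_snp[i]) "snp_overlap"
        else if (nc[id] > thr) "negative_control_high"
        else if (mean(detp[i, ] <= 0.05) < 0.70) "low_detection"
        else NA_character_
      if (!is.na(r)) oracle[id] <- r
    }
    expect_identical(setNames(got$report$reason, got$report$id), oracle)
    expect_identical(rownames(got$beta$values), setdiff(rownames(v), names(oracle)))
  }
})

test_that("probe detection rule uses < 70% detected and p <= 0.05 as detected", {
  ns <- 100
  v <- matrix(0.5, nrow = 2, ncol = ns,
              dimnames = list(c("c1", "c2"), sprintf("S%03d", 1:ns)))
  detp <- v
  detp["c1", ] <- c(rep(0.04, 69), rep(0.9, 31))  # detected in 69% -> out
  detp["c2", ] <- c(rep(0.05, 70), rep(0.9, 30))  # exactly 70% -> kept
  got <- filter_probes(beta_matrix(v, detection_p = detp))
  expect_identical(got$report$id, "c1")
  expect_identical(got$report$reason, "low_detection")
  expect_identical(rownames(got$beta$values), "c2")
})

test_that("sample filter uses a strict > 25% failed rule and matches brute force", {
  n <- 200
  v <- matrix(0.5, nrow = n, ncol = 3,
              dimnames = list(sprintf("c%03d", 1:n), c("bad", "edge", "good")))
  detp <- v
  detp[, "bad"] <- c(rep(1e-4, 52), rep(1e-9, n - 52))   # 26% failed
  detp[, "edge"] <- c(rep(1e-4, 50), rep(1e-9, n - 50))  # exactly 25%
  detp[, "good"] <- 1e-9
  got <- filter_samples(beta_matrix(v, detection_p = detp))
  expect_identical(got$report$id, "bad")
  expect_identical(colnames(got$beta$values), c("edge", "good"))

  set.seed(9)
  detp2 <- matrix(sample(c(1e-9, 1e-3), n * 10, TRUE, prob = c(0.78, 0.22)),
                  nrow = n,
                  dimnames = list(rownames(v), sprintf("S%02d", 1:10)))
  v2 <- matrix(0.5, n, 10, dimnames = dimnames(detp2))
  got2 <- filter_samples(beta_matrix(v2, detection_p = detp2))
  oracle <- colnames(v2)[colMeans(detp2 > 1e-5) > 0.25]
  expect_identical(got2$report$id, oracle)

  # degenerate: every sample failing leaves an empty, well-formed matrix
  all_bad <- beta_matrix(v2, detection_p = matrix(0.5, n, 10,
                                                  dimnames = dimnames(v2)))
  got3 <- filter_samples(all_bad)
  expect_identical(ncol(got3$beta$values), 0L)
  expect_identical(got3$report$id, colnames(v2))
})

test_that("HWE chi-square test matches closed forms", {
  p <- hwe_test(25, 50, 25)
  expect_equal(as.numeric(p), 1)
  expect_equal(attr(p, "statistic"), 0)

  p2 <- hwe_test(0, 100, 0)  # chi-square = 100
  expect_equal(attr(p2, "statistic"), 100)
  expect_lt(as.numeric(p2), 1e-4)

  p3 <- hwe_test(50, 0, 50)
  expect_lt(as.numeric(p3), 1e-4)

  expect_equal(as.numeric(hwe_test(10, 0, 0)), 1)  # monomorphic convention
})

test_that("SNP filters match brute force with strict boundaries and fixed rule order", {
  set.seed(5)
  n <- 200
  maf_exact <- 0.05
  d <- cbind(
    missing6 = replace(rbinom(n, 2, 0.3), 1:12, NA),            # 6% missing
    maf_edge = c(rep(1, round(2 * n * maf_exact)), rep(0, n - round(2 * n * maf_exact))),
    hwe_bad = rep(1, n),                                         # all hets
    fine = rbinom(n, 2, 0.4)
  )
  rownames(d) <- sprintf("S%03d", 1:n)
  g <- genotype_matrix(d)
  got <- filter_snps(g)
  expect_identical(setNames(got$report$reason, got$report$id),
                   c(missing6 = "call_rate", hwe_bad = "hwe"))
  # MAF exactly 0.05 is retained (strict <)
  expect_true("maf_edge" %in% colnames(got$geno$dosages))

  # randomized equivalence with a rule-by-rule oracle
  for (seed in 1:3) {
    set.seed(seed)
    d2 <- vapply(runif(30, 0.01, 0.5), function(p) {
      x <- rbinom(n, 2, p)
      x[runif(n) < 0.03] <- NA
      x
    }, numeric(n))
    dimnames(d2) <- list(rownames(d), sprintf("snp%02d", 1:30))
    got2 <- filter_snps(genotype_matrix(d2))
    oracle <- apply(d2, 2, function(x) {
      if (mean(!is.na(x)) < 0.95) return("call_rate")
      x <- x[!is.na(x)]
      f <- mean(x) / 2
      if (min(f, 1 - f) < 0.05) return("maf")
      p <- as.numeric(hwe_test(sum(x == 0), sum(x == 1), sum(x == 2)))
      if (p < 1e-4) return("hwe")
      NA_character_
    })
    expect_identical(setNames(got2$report$reason, got2$report$id),
                     oracle[!is.na(oracle)])
  }
})

test_that("QC filters are idempotent", {
  b <- make_toy_beta(40, 12, seed = 11)
  once <- filter_probes(b)$beta
  twice <- filter_probes(once)$beta
  expect_identical(twice$values, once$values)
  s_once <- filter_samples(b)$beta
  expect_identical(filter_samples(s_once)$beta$values, s_once$values)
})

test_that("PCA diagnostics expose a planted two-group shift and order components", {
  set.seed(21)
  n <- 40; np <- 100
  batch <- rep(c("B1", "B2"), each = n / 2)
  M <- matrix(rnorm(np * n, sd = 0.3), nrow = np,
              dimnames = list(paste0("c", 1:np), sprintf("S%04d", 1:n)))
  M[, batch == "B2"] <- M[, batch == "B2"] + 2
  samples <- make_toy_samples(n)
  samples$batch <- batch
  pd <- pca_diagnostics(mvalue_matrix(M), samples, n_components = 4)
  expect_lt(pd$summary$p_batch[1], 1e-10)
  # independent check: two-sample t on PC1 scores
  tt <- t.test(pd$scores$PC1 ~ batch)
  expect_lt(tt$p.value, 1e-10)
  expect_true(all(diff(pd$summary$variance_fraction) <= 1e-12))
  expect_lte(sum(pd$summary$variance_fraction), 1 + 1e-8)

  const <- mvalue_matrix(matrix(1, 5, 10,
                                dimnames = list(paste0("c", 1:5),
                                                samples$sample_id[1:10])))
  expect_error(pca_diagnostics(const, samples[1:10, ]), "constant")
})

test_that("batch adjustment removes a constant shift and preserves null data", {
  set.seed(31)
  n <- 40; np <- 120
  samples <- make_toy_samples(n)
  samples$batch <- rep(c("B1", "B2"), each = n / 2)
  # batch 2 duplicates batch 1 plus a constant shift; probe SDs equalised
  # so the empirical-Bayes location estimates are exact, not shrunk
  base <- t(scale(t(matrix(rnorm(np * n / 2), nrow = np)))) * 0.5
  delta <- 1.5
  M1 <- cbind(base, base + delta)
  dimnames(M1) <- list(paste0("c", 1:np), samples$sample_id)
  adj <- combat_adjust(mvalue_matrix(M1), samples, protect = character(0))
  gap <- rowMeans(adj$values[, samples$batch == "B1"]) -
    rowMeans(adj$values[, samples$batch == "B2"])
  expect_lt(max(abs(gap)), 1e-6)

  # no batch effect: output stays essentially the input
  n2 <- 800
  s2 <- make_toy_samples(n2)
  s2$batch <- rep(c("B1", "B2"), each = n2 / 2)
  s2$case_status <- rep(c(1L, 0L), n2 / 2)  # balanced within batch
  M0 <- matrix(rnorm(150 * n2, 0, 0.5), nrow = 150,
               dimnames = list(paste0("c", 1:150), s2$sample_id))
  adj0 <- combat_adjust(mvalue_matrix(M0), s2)
  cors <- vapply(1:150, function(i) cor(adj0$values[i, ], M0[i, ]),
                 numeric(1))
  expect_gt(min(cors), 0.999)

  # singleton batch refused
  s_bad <- samples
  s_bad$batch <- c("B9", samples$batch[-1])
  expect_error(combat_adjust(mvalue_matrix(M1), s_bad), "at least 2 samples")
})

test_that("batch adjustment preserves a planted case effect within 10%", {
  set.seed(33)
  n <- 80; np <- 150
  samples <- make_toy_samples(n)
  samples$batch <- rep(c("B1", "B2"), each = n / 2)
  samples$case_status <- rep(c(1L, 0L), n / 2)  # balanced across batches
  eff <- 0.8
  M <- matrix(rnorm(np * n, sd = 0.5), nrow = np,
              dimnames = list(paste0("c", 1:np), samples$sample_id))
  M[1:30, samples$case_status == 1] <- M[1:30, samples$case_status == 1] + eff
  M[, samples$batch == "B2"] <- M[, samples$batch == "B2"] + 1
  adj <- combat_adjust(mvalue_matrix(M), samples)
  slope <- function(vals, i) unname(coef(lm(vals[i, ] ~ samples$case_status))[2])
  before <- vapply(1:30, function(i) slope(M, i), numeric(1))
  after <- vapply(1:30, function(i) slope(adj$values, i), numeric(1))
  expect_lt(mean(abs(after - before) / abs(before)), 0.10)
})

test_that("plate residualisation equalises plate means and keeps the grand mean", {
  v <- matrix(c(1, 1, 3, 3,
                2, 4, 2, 4), nrow = 2, byrow = TRUE,
              dimnames = list(c("c1", "c2"), sprintf("S%04d", 1:4)))
  samples <- make_toy_samples(4)
  samples$plate <- c("P1", "P1", "P2", "P2")
  out <- plate_residualize(mvalue_matrix(v), samples)
  # closed form: plates with means 1 and 3 both land on the grand mean 2
  expect_equal(unname(out$values["c1", ]), rep(2, 4))
  expect_equal(mean(out$values["c2", ]), mean(v["c2", ]), tolerance = 1e-10)
  for (pl in c("P1", "P2")) {
    expect_equal(mean(out$values["c2", samples$plate == pl]),
                 mean(out$values["c2", ]), tolerance = 1e-10)
  }

  # no plate effect: output equals input
  set.seed(7)
  v2 <- matrix(rnorm(40), nrow = 4,
               dimnames = list(paste0("c", 1:4), sprintf("S%04d", 1:10)))
  s2 <- make_toy_samples(10)
  s2$plate <- rep(c("P1", "P2"), 5)
  centered <- v2
  for (pl in c("P1", "P2")) {
    idx <- s2$plate == pl
    centered[, idx] <- centered[, idx] - rowMeans(v2[, idx]) + rowMeans(v2)
  }
  out2 <- plate_residualize(mvalue_matrix(centered), s2)
  expect_equal(out2$values, centered, tolerance = 1e-10)
})
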