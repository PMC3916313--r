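config_defaults <- function() {
  list(
    alpha_ewas_q = 0.05, alpha_meqtl_q = 0.10, alpha_snp_p = 0.05,
    alpha_cit = 0.05, alpha_p4 = 0.05,
    detection_alpha = 0.05, min_detected = 0.70,
    sample_detection_threshold = 1e-5, sample_max_failed = 0.25,
    min_call_rate = 0.95, min_maf = 0.05, hwe_alpha = 1e-4,
    nc_sd_mult = 4, logit_clip = 0.001, k_probes = 100,
    seed = 1L, log_level = "info"
  )
}

#' Load a run configuration from YAML
#'
#' Unknown keys are rejected; every threshold must lie in (0, 1); keys
#' absent from the file take the pipeline defaults (EWAS q < 0.05, meQTL
#' q < 0.10, SNP p < 0.05, CIT p < 0.05). An empty or missing-body file
#' yields the full default configuration. An optional `simulation` block
#' is passed to [simulation_config()].
#'
#' @param path YAML file.
#' @return A list of class `run_config` with every key resolved.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- config_defaults()
  sim <- raw$simulation
  raw$simulation <- NULL
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, raw)
  fractional <- c("alpha_ewas_q", "alpha_meqtl_q", "alpha_snp_p", "alpha_cit",
                  "alpha_p4", "detection_alpha", "min_detected",
                  "sample_max_failed", "min_call_rate", "min_maf", "hwe_alpha")
  for (key in fractional) {
    v <- cfg[[key]]
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      abort(sprintf("config key `%s` must lie strictly within (0, 1); got %s",
                    key, format(v)))
    }
  }
  if (!is.null(sim)) {
    # YAML maps arrive as lists; generator fields are atomic vectors
    sim <- lapply(sim, function(x) if (is.list(x)) unlist(x) else x)
    cfg$simulation <- do.call(simulation_config, sim)
  }
  structure(cfg, class = "run_config")
}

#' Write a resolved run configuration to YAML
#' @param cfg A `run_config` from [load_config()].
#' @param path Output YAML file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  if (!is.null(out$simulation)) {
    # named vectors must become maps, or YAML drops their names
    out$simulation <- lapply(unclass(out$simulation), function(x) {
      if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
    })
  }
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Cascade config from a run config
#' @param cfg A `run_config`.
#' @return A [cascade_config()].
#' @export
as_cascade_config <- function(cfg) {
  cascade_config(
    alpha_ewas_q = cfg$alpha_ewas_q, alpha_meqtl_q = cfg$alpha_meqtl_q,
    alpha_snp_p = cfg$alpha_snp_p, alpha_cit = cfg$alpha_cit,
    alpha_p4 = cfg$alpha_p4, k_probes = cfg$k_probes
  )
}

#' Write a machine-readable run report
#'
#' Serialises the cascade stage counts together with the seed, package
#' version and a hash of the resolved configuration, so identical inputs
#' and seed produce byte-identical reports.
#'
#' @param result A `cascade_result` from [run_cascade()].
#' @param path Output TSV file.
#' @param seed The seed the run used.
#' @param cfg Optional `run_config` or [cascade_config()]; hashed into
#'   the report.
#' @return The report tibble, invisibly.
#' @export
run_report <- function(result, path, seed = NA_integer_, cfg = NULL) {
  meta <- tibble::tibble(
    stage = c("meta_seed", "meta_package_version", "meta_config_hash"),
    count = NA_integer_,
    value = c(as.character(seed),
              as.character(utils::packageVersion("citewas")),
              if (is.null(cfg)) "" else config_hash(cfg))
  )
  counts <- result$report
  counts$value <- ""
  report <- dplyr::bind_rows(counts, meta)
  write_results(report, path)
  invisible(report)
}

# Stable content hash of a config: deterministic across sessions, no
# dependency on serialisation internals.
config_hash <- function(cfg) {
  flat <- unlist(unclass(cfg), use.names = TRUE)
  s <- paste(names(flat), vapply(flat, format, character(1), digits = 15),
             sep = "=", collapse = ";")
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%010d", h)
}
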