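#' Tidy a cascade result
#'
#' Returns the trio-level table (one row per CIT-tested CpG-SNP pair), or
#' an empty tibble when the cascade terminated before the CIT stage.
#'
#' @param x A `cascade_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cascade_result
#' @export
tidy.cascade_result <- function(x, ...) {
  if (is.null(x$trios)) return(tibble::tibble())
  tibble::as_tibble(x$trios)
}

#' One-row summary of a cascade run
#'
#' @param x A `cascade_result`.
#' @param ... Unused.
#' @return A one-row tibble with the Figure-style funnel counts.
#' @method glance cascade_result
#' @export
glance.cascade_result <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$report, names_from = "stage",
                             values_from = "count")
  wide$n_mediated_pairs <- x$mediated$n_pairs
  wide$n_mediated_cpgs <- x$mediated$n_cpgs
  wide$n_mediated_snps <- x$mediated$n_snps
  wide
}

#' @method tidy ewas_result
#' @export
tidy.ewas_result <- function(x, ...) tibble::as_tibble(x)

#' @method glance ewas_result
#' @export
glance.ewas_result <- function(x, ...) {
  tibble::tibble(
    n_cpgs = nrow(x),
    n_q_lt_05 = sum(x$q_value < 0.05),
    min_p = min(x$p_value),
    pi0_hat = estimate_pi0(x$p_value)
  )
}

#' @method tidy trio_result
#' @export
tidy.trio_result <- function(x, ...) tibble::as_tibble(x)

#' @method glance trio_result
#' @export
glance.trio_result <- function(x, ...) {
  tibble::tibble(
    n_trios = nrow(x),
    n_mediated = sum(x$label == "mediated"),
    n_separation_flagged = sum(x$separation_flag)
  )
}
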