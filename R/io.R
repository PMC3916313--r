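#' Read a methylation beta matrix from TSV
#'
#' Expects a tab-delimited file with a header row of sample ids and the
#' probe id in the first column. An optional second file of identical
#' layout supplies detection p-values; an optional annotation file supplies
#' per-probe annotation.
#'
#' @param path TSV file of beta values.
#' @param detection_path Optional TSV file of detection p-values.
#' @param annotation_path Optional TSV file of probe annotation with a
#'   `probe_id` column.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path, detection_path = NULL,
                             annotation_path = NULL) {
  values <- read_id_matrix(path)
  detection_p <- if (!is.null(detection_path)) read_id_matrix(detection_path)
  probes <- if (!is.null(annotation_path)) {
    readr::read_tsv(annotation_path, show_col_types = FALSE)
  }
  beta_matrix(values, probes = probes, detection_p = detection_p)
}

#' Write a beta or M-value matrix to TSV
#'
#' @param x A [beta_matrix()] or [mvalue_matrix()].
#' @param path Output file; the detection layer, if present, goes to
#'   `detection_path`.
#' @param detection_path Optional output file for detection p-values.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path, detection_path = NULL) {
  write_id_matrix(x$values, path)
  if (!is.null(detection_path) && !is.null(x$detection_p)) {
    write_id_matrix(x$detection_p, detection_path)
  }
  invisible(path)
}

#' Read a genotype matrix from a TSV dosage file or a VCF
#'
#' TSV files carry samples in the header and one SNP per row (first column
#' the SNP id), holding integer dosages or `NA`. VCF files (v4.x) must be
#' biallelic with diploid `GT` fields. In both cases dosages are re-coded
#' as minor-allele counts against the allele frequencies observed in the
#' file: if the ALT (or counted) allele has frequency above 0.5 it is the
#' major allele and dosages are flipped to `2 - dosage`. Exact ties
#' (frequency 0.5) designate ALT as minor, deterministically.
#'
#' @param path TSV or VCF file; VCF detected by `.vcf` extension or
#'   `##fileformat=VCF` first line.
#' @return A [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\\.vcf(\\.gz)?$", path) || grepl("^##fileformat=VCF", first)) {
    read_genotype_vcf(path)
  } else {
    read_genotype_tsv(path)
  }
}

read_genotype_tsv <- function(path) {
  m <- read_id_matrix(path)
  bad <- !is.na(m) & !(m %in% c(0, 1, 2))
  if (any(bad)) {
    abort(sprintf("dosage file contains value %g outside {0, 1, 2, NA}",
                  m[bad][1]))
  }
  # rows are SNPs on disk; flip to samples x SNPs and re-code to minor allele
  d <- t(m)
  d <- recode_minor(d)
  genotype_matrix(d$dosages,
    snps = tibble::tibble(
      snp_id = colnames(d$dosages), chr = NA_character_, pos = NA_integer_,
      alleles = NA_character_,
      minor_allele = unname(ifelse(d$flipped, "REF", "ALT"))
    )
  )
}

read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record files come back as a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    abort(sprintf("multiallelic VCF record at %s:%s not supported",
                  fix$CHROM[multi][1], fix$POS[multi][1]))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- strsplit(gsub("\\|", "/", as.vector(gt)), "/", fixed = TRUE)
  n_allele <- lengths(alleles)
  called <- !is.na(as.vector(gt)) & as.vector(gt) != "."
  if (any(called & n_allele != 2L)) {
    abort("non-diploid GT field encountered; only diploid calls supported.")
  }
  alt_count <- vapply(alleles, function(a) {
    if (length(a) != 2L || any(a == ".")) return(NA_real_)
    sum(a == "1")
  }, numeric(1))
  if (any(!is.na(alt_count) &
          !vapply(alleles, function(a) all(a %in% c("0", "1", ".")), logical(1)))) {
    abort("GT allele codes other than 0/1 found; only biallelic records supported.")
  }
  m <- matrix(alt_count, nrow = nrow(gt), ncol = ncol(gt),
              dimnames = dimnames(gt))
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  rownames(m) <- ids
  d <- recode_minor(t(m))
  genotype_matrix(d$dosages,
    snps = tibble::tibble(
      snp_id = colnames(d$dosages),
      chr = fix$CHROM, pos = as.integer(fix$POS),
      alleles = paste0(fix$REF, "/", fix$ALT),
      minor_allele = unname(ifelse(d$flipped, fix$REF, fix$ALT))
    )
  )
}

# Flip columns whose counted-allele frequency exceeds 0.5 so dosages count
# the minor allele; frequency exactly 0.5 keeps the counted (ALT) allele.
recode_minor <- function(dosages) {
  freq <- colMeans(dosages, na.rm = TRUE) / 2
  flipped <- !is.na(freq) & freq > 0.5
  dosages[, flipped] <- 2 - dosages[, flipped, drop = FALSE]
  list(dosages = dosages, flipped = flipped)
}

#' Read a leukocyte reference panel from TSV
#'
#' The file must carry a `probe_id` first column and exactly the six
#' canonical cell-type columns `CD8T, CD4T, NK, Bcell, Mono, Gran`.
#'
#' @param path TSV file.
#' @return A [reference_panel()].
#' @export
read_reference_panel <- function(path) {
  m <- read_id_matrix(path)
  reference_panel(m)
}

#' Write a reference panel to TSV
#' @param panel A [reference_panel()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reference_panel <- function(panel, path) {
  write_id_matrix(panel$means, path, id_col = "probe_id")
  invisible(path)
}

#' Read a sample covariate table from TSV
#' @param path TSV file with a header; must contain `sample_id` and
#'   `case_status` columns.
#' @return A validated tibble.
#' @export
read_sample_table <- function(path) {
  validate_sample_table(readr::read_tsv(path, show_col_types = FALSE))
}

#' Write a result table to TSV
#'
#' Deterministic column order (as given), `NA` for missing values, floats
#' serialised with full precision so the file re-reads to the same values
#' within serialisation accuracy.
#'
#' @param table A data frame of results.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path, na = "NA")
  invisible(path)
}

#' Read a result table written by [write_results()]
#' @param path TSV file.
#' @return A tibble.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

read_id_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, na = "NA",
                        name_repair = "minimal")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  m
}

write_id_matrix <- function(m, path, id_col = "probe_id") {
  df <- tibble::as_tibble(m, rownames = id_col)
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}
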