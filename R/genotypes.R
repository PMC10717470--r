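#' Construct a genotype matrix object
#'
#' A light container for SNP genotypes: an integer matrix of reference-allele
#' counts (0/1/2, `NA` = missing call) with sample ids as row names and SNP
#' ids as column names.
#'
#' @param calls Numeric matrix of 0/1/2 calls (NA allowed).
#' @param sample_ids,snp_ids Optional identifier vectors; default to the
#'   dimnames of `calls`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, sample_ids = rownames(calls),
                            snp_ids = colnames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(sample_ids)) sample_ids <- paste0("ind", seq_len(nrow(calls)))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(calls)))
  if (length(sample_ids) != nrow(calls) || length(snp_ids) != ncol(calls)) {
    abort("id lengths must match the call matrix dimensions.")
  }
  if (anyDuplicated(sample_ids)) abort("duplicated sample ids.")
  if (anyDuplicated(snp_ids)) abort("duplicated SNP ids.")
  bad <- !is.na(calls) & !calls %in% c(0, 1, 2)
  if (any(bad)) abort("genotype calls must be 0, 1, 2 or missing.")
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(as.character(sample_ids), as.character(snp_ids))
  structure(calls, class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix: %d individuals x %d SNPs, %.2f%% missing>\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Read genotypes from TSV or PLINK .raw files
#'
#' The `tsv` dialect is a plain table: first column sample id, remaining
#' columns one SNP each (header = SNP ids). The `plink_raw` dialect is the
#' additive-recode export of PLINK: columns FID IID PAT MAT SEX PHENOTYPE
#' followed by one allele-count column per SNP; IID is used as the sample id.
#' Unparseable cells become missing calls with a reported count.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"plink_raw"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("tsv", "plink_raw")) {
  dialect <- match.arg(dialect)
  tab <- readr::read_delim(path, delim = if (dialect == "tsv") "\t" else " ",
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  if (dialect == "plink_raw") {
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(meta %in% names(tab))) {
      abort("plink_raw file must carry FID IID PAT MAT SEX PHENOTYPE columns.")
    }
    ids <- tab$IID
    snp_cols <- setdiff(names(tab), meta)
  } else {
    ids <- tab[[1L]]
    snp_cols <- names(tab)[-1L]
  }
  if (length(snp_cols) == 0L) abort("no SNP columns found.")
  raw <- as.matrix(tab[snp_cols])
  suppressWarnings(num <- matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  unparseable <- sum(!is.na(raw) & raw != "NA" & is.na(num))
  num[!num %in% c(0, 1, 2)] <- NA
  if (unparseable > 0L) {
    inform(sprintf("read_genotypes: %d unparseable cell(s) set to missing.",
                   unparseable))
  }
  genotype_matrix(num, sample_ids = ids, snp_ids = snp_cols)
}

#' Write genotypes as a TSV round-trippable with [read_genotypes()]
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  tab <- tibble::as_tibble(unclass(g))
  tab <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(g)), tab)
  readr::write_tsv(tab, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Per-SNP allele frequencies
#'
#' Frequency p of the counted (A1) allele at each SNP, computed over
#' non-missing calls only: p_i = sum(calls_i) / (2 * n_nonmissing_i).
#'
#' @param g A [genotype_matrix()].
#' @return A tibble with columns `snp`, `p`, `q` (= 1 - p), `n_called`.
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  n_called <- colSums(!is.na(g))
  if (any(n_called == 0L)) {
    abort(sprintf("SNP(s) with no non-missing calls: %s",
                  paste(colnames(g)[n_called == 0L], collapse = ", ")))
  }
  p <- colSums(g, na.rm = TRUE) / (2 * n_called)
  tibble::tibble(snp = colnames(g), p = unname(p), q = 1 - unname(p),
                 n_called = unname(n_called))
}

#' Hardy-Weinberg goodness-of-fit chi-square test
#'
#' One-degree-of-freedom chi-square test of genotype counts against
#' Hardy-Weinberg proportions at the observed allele frequency, without
#' continuity correction. Monomorphic counts give a statistic of 0.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (A = counted allele).
#' @return A list with `chi_square` and `p_value`.
#' @export
#' @examples
#' hwe_chi_square(25, 50, 25) # exact HWE: chi-square 0
hwe_chi_square <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(is.na(counts))) abort("counts must be non-negative.")
  n <- sum(counts)
  if (n == 0) abort("total genotype count must be positive.")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(list(chi_square = 0, p_value = 1))
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi <- sum((counts - expected)^2 / expected)
  list(chi_square = chi, p_value = pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Apply genotype quality control
#'
#' Single-pass filtering in fixed order: (1) individuals failing the call
#' rate (when enabled); (2) SNPs, evaluated on the surviving individuals:
#' call rate, minor allele frequency, Hardy-Weinberg p-value (when enabled).
#' Monomorphic SNPs are always removed: they contribute nothing to any
#' relationship-matrix denominator and break the dominance coding.
#'
#' @param g A [genotype_matrix()].
#' @param snp_call_rate_min Minimum SNP call rate (proportion).
#' @param maf_min Minimum minor allele frequency.
#' @param hwe_p_min Minimum HWE p-value, or `NULL` to skip the test.
#' @param individual_call_rate_min Minimum individual call rate, or `NULL`.
#' @return A list with `genotypes` (filtered matrix) and `report`, a tibble
#'   of per-filter removal counts plus in/out dimensions.
#' @export
apply_qc <- function(g, snp_call_rate_min = 0.9, maf_min = 0.01,
                     hwe_p_min = 1e-5, individual_call_rate_min = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  check_proportion(snp_call_rate_min, "snp_call_rate_min")
  check_proportion(maf_min, "maf_min")
  if (!is.null(hwe_p_min)) check_proportion(hwe_p_min, "hwe_p_min")
  if (!is.null(individual_call_rate_min)) {
    check_proportion(individual_call_rate_min, "individual_call_rate_min")
  }
  n_ind_in <- nrow(g); n_snp_in <- ncol(g)

  ind_removed <- 0L
  if (!is.null(individual_call_rate_min)) {
    cr <- rowMeans(!is.na(g))
    keep <- cr >= individual_call_rate_min
    ind_removed <- sum(!keep)
    if (!any(keep)) abort("all individuals removed by call-rate filter.")
    g <- genotype_matrix(g[keep, , drop = FALSE])
  }

  # SNP filters on the matrix entering after individual removal
  cr <- colMeans(!is.na(g))
  fail_cr <- cr < snp_call_rate_min
  called <- colSums(!is.na(g))
  p <- ifelse(called > 0, colSums(g, na.rm = TRUE) / (2 * pmax(called, 1L)), NA)
  maf <- pmin(p, 1 - p)
  fail_mono <- is.na(p) | p == 0 | p == 1
  fail_maf <- !fail_mono & maf < maf_min
  fail_hwe <- rep(FALSE, ncol(g))
  if (!is.null(hwe_p_min)) {
    for (j in which(!fail_mono & !fail_cr & !fail_maf)) {
      x <- g[, j]
      pv <- hwe_chi_square(sum(x == 2, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                           sum(x == 0, na.rm = TRUE))$p_value
      fail_hwe[j] <- pv < hwe_p_min
    }
  }
  keep <- !(fail_cr | fail_mono | fail_maf | fail_hwe)
  if (!any(keep)) abort("all SNPs removed by quality control.")
  out <- genotype_matrix(g[, keep, drop = FALSE])

  report <- tibble::tibble(
    filter = c("individual_call_rate", "snp_call_rate", "monomorphic",
               "maf", "hwe"),
    threshold = c(individual_call_rate_min %||% NA_real_, snp_call_rate_min,
                  NA_real_, maf_min, hwe_p_min %||% NA_real_),
    removed = c(ind_removed, sum(fail_cr), sum(fail_mono & !fail_cr),
                sum(fail_maf & !fail_cr), sum(fail_hwe))
  )
  attr(report, "n_individuals_in") <- n_ind_in
  attr(report, "n_individuals_out") <- nrow(out)
  attr(report, "n_snps_in") <- n_snp_in
  attr(report, "n_snps_out") <- ncol(out)
  list(genotypes = out, report = report)
}

# Dosage matrix with missing calls imputed at the per-SNP mean 2p (the
# frequency expectation), ready for relationship-matrix construction.
imputed_dosage <- function(g, freqs) {
  X <- matrix(as.numeric(g), nrow(g), ncol(g), dimnames = dimnames(g))
  if (anyNA(X)) {
    mu <- 2 * freqs$p
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2L]]
  }
  X
}
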