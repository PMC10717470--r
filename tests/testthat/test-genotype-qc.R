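test_that("genotype TSV round-trips losslessly, including missing cells", {
  g <- genotype_matrix(matrix(c(2, 1, 0, NA, 1, 2, 0, 0, 1, 2, NA, 0), 3, 4),
                       sample_ids = c("a", "b", "c"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  g2 <- read_genotypes(path, dialect = "tsv")
  expect_identical(unclass(g2), unclass(g))
})

test_that("plink_raw dialect parses headers and allele counts", {
  path <- withr::local_tempfile(fileext = ".raw")
  writeLines(c(
    "FID IID PAT MAT SEX PHENOTYPE snp1_A snp2_C",
    "f1 ind1 0 0 1 -9 2 0",
    "f2 ind2 0 0 2 -9 1 NA"
  ), path)
  g <- read_genotypes(path, dialect = "plink_raw")
  expect_equal(rownames(g), c("ind1", "ind2"))
  expect_equal(colnames(g), c("snp1_A", "snp2_C"))
  expect_equal(unname(g["ind2", ]), c(1L, NA))
})

test_that("unparseable cells become missing with a message", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ts1\ts2", "a\t2\toops", "b\t1\t0"), path)
  expect_message(g <- read_genotypes(path), "unparseable")
  expect_true(is.na(g["a", "s2"]))
  expect_equal(g["b", "s2"], 0L, ignore_attr = TRUE)
})

test_that("duplicated ids are rejected", {
  expect_error(genotype_matrix(matrix(0L, 2, 1), sample_ids = c("a", "a")),
               "duplicated")
  expect_error(genotype_matrix(matrix(0L, 1, 2), snp_ids = c("s", "s")),
               "duplicated")
})

test_that("allele frequencies use non-missing calls only", {
  g <- genotype_matrix(cbind(c(2, 1, 0), c(2, 2, 2), c(2, 1, NA)))
  fr <- allele_frequencies(g)
  expect_equal(fr$p, c(0.5, 1, 3 / 4))
  expect_equal(fr$p + fr$q, rep(1, 3))
  g_allna <- genotype_matrix(cbind(c(1, 1), c(NA, NA)))
  expect_error(allele_frequencies(g_allna), "snp2")
})

test_that("HWE chi-square matches hand computations", {
  expect_equal(hwe_chi_square(25, 50, 25),
               list(chi_square = 0, p_value = 1))
  expect_equal(hwe_chi_square(50, 0, 50)$chi_square, 100)
  expect_equal(hwe_chi_square(0, 100, 0)$chi_square, 100)
  expect_error(hwe_chi_square(-1, 2, 3), "non-negative")
  expect_error(hwe_chi_square(0, 0, 0), "positive")
})

test_that("QC removes exactly the failing SNPs, in the documented order", {
  # 400 individuals: SNP columns engineered per filter
  set.seed(201)
  n <- 400
  good <- rbinom(n, 2, 0.3)
  low_maf <- rbinom(n, 2, 0.005)        # MAF ~ 0.005 < 0.01
  mono <- rep(2L, n)                    # monomorphic
  low_cr <- ifelse(runif(n) < 0.2, NA, rbinom(n, 2, 0.4)) # call rate ~0.8
  anti_hwe <- rep(c(0L, 2L), n / 2)     # no heterozygotes at p = 0.5
  g <- genotype_matrix(cbind(good = good, low_maf = low_maf, mono = mono,
                             low_cr = low_cr, anti_hwe = anti_hwe))
  res <- apply_qc(g, snp_call_rate_min = 0.9, maf_min = 0.01,
                  hwe_p_min = 1e-5)
  expect_equal(colnames(res$genotypes), "good")
  rep <- res$report
  expect_equal(rep$removed[rep$filter == "maf"], 1)
  expect_equal(rep$removed[rep$filter == "monomorphic"], 1)
  expect_equal(rep$removed[rep$filter == "snp_call_rate"], 1)
  expect_equal(rep$removed[rep$filter == "hwe"], 1)
  expect_equal(attr(rep, "n_snps_in") - sum(rep$removed[-1]),
               attr(rep, "n_snps_out"))
})

test_that("zero thresholds are the identity and QC is idempotent", {
  set.seed(7)
  g <- genotype_matrix(matrix(rbinom(200, 2, 0.4), 20, 10))
  res0 <- apply_qc(g, snp_call_rate_min = 0, maf_min = 0, hwe_p_min = NULL)
  expect_identical(unclass(res0$genotypes), unclass(g))
  expect_equal(sum(res0$report$removed), 0)
  once <- apply_qc(g, snp_call_rate_min = 0.9, maf_min = 0.05,
                   hwe_p_min = 1e-5, individual_call_rate_min = 0.9)
  twice <- apply_qc(once$genotypes, snp_call_rate_min = 0.9, maf_min = 0.05,
                    hwe_p_min = 1e-5, individual_call_rate_min = 0.9)
  expect_identical(unclass(twice$genotypes), unclass(once$genotypes))
  expect_equal(sum(twice$report$removed), 0)
})

test_that("individual call-rate filter runs before SNP filters", {
  # individual "bad" is mostly missing and drags SNP call rates down;
  # once removed, all SNPs pass
  set.seed(31)
  calls <- matrix(rbinom(5 * 10, 2, 0.4), 5, 10)
  calls[5, 1:8] <- NA
  g <- genotype_matrix(calls, sample_ids = c(paste0("ok", 1:4), "bad"))
  res <- apply_qc(g, snp_call_rate_min = 0.9, maf_min = 0, hwe_p_min = NULL,
                  individual_call_rate_min = 0.5)
  expect_false("bad" %in% rownames(res$genotypes))
  expect_equal(res$report$removed[res$report$filter == "individual_call_rate"], 1)
})
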