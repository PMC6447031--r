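two_snp_weights <- function() {
  tibble::tibble(rsid = c("a", "b"), effect_allele = c("A", "G"),
                 beta = c(0.1, 0.2), maf = c(0.3, 0.25))
}

test_that("the score is the weighted dosage sum", {
  w <- two_snp_weights()
  g <- tibble::tibble(patient_id = c("p1", "p2"), a = c(2, 0), b = c(1, 0))
  s <- compute_grs(g, w)
  expect_equal(s$grs, c(0.4, 0))
  expect_equal(s$n_snps_used, c(2L, 2L))
})

test_that("missing dosages impute at 2*maf and are counted", {
  w <- two_snp_weights()
  g <- tibble::tibble(patient_id = "p1", a = 1, b = NA_real_)
  s <- compute_grs(g, w)
  # Hardy-Weinberg expectation for b: E[dosage] = 2 * 0.25 = 0.5, checked
  # against the explicit genotype-frequency expectation
  e_dosage <- sum(0:2 * c(0.75^2, 2 * 0.25 * 0.75, 0.25^2))
  expect_equal(e_dosage, 0.5)
  expect_equal(s$grs, 0.1 * 1 + 0.2 * e_dosage)
  expect_equal(s$n_snps_used, 1L)
})

test_that("weights without genotype columns are skipped with a warning", {
  w <- dplyr::bind_rows(two_snp_weights(),
                        tibble::tibble(rsid = "zzz", effect_allele = "T",
                                       beta = 9, maf = 0.1))
  g <- tibble::tibble(patient_id = "p1", a = 2, b = 1)
  expect_warning(s <- compute_grs(g, w), "zzz")
  expect_equal(s$grs, 0.4)
  expect_equal(attr(s, "skipped_snps"), "zzz")
})

test_that("the score is linear and order-invariant", {
  set.seed(3)
  w <- default_snp_weights()[1:10, ]
  g <- tibble::tibble(patient_id = sprintf("p%d", 1:20))
  for (r in w$rsid) g[[r]] <- rbinom(20, 2, 0.3)
  s1 <- compute_grs(g, w)
  s2 <- compute_grs(g, w |> dplyr::mutate(beta = 2 * beta))
  expect_equal(s2$grs, 2 * s1$grs)
  perm <- w[sample(nrow(w)), ]
  expect_equal(compute_grs(g, perm)$grs, s1$grs)
  # with complete data the imputation path leaves results untouched
  expect_equal(s1$grs, as.numeric(as.matrix(g[, w$rsid]) %*% w$beta))
})

test_that("dosages outside [0, 2] are rejected", {
  w <- two_snp_weights()
  expect_error(compute_grs(tibble::tibble(patient_id = "p1", a = 3, b = 0), w),
               class = "sepsisldl_param_error")
})

test_that("validation reports r and r2 on the overlap", {
  set.seed(4)
  ldl <- tibble::tibble(patient_id = sprintf("p%d", 1:10000),
                        ldl_baseline = rnorm(10000, 103, 33))
  # perfect correlation
  s_perfect <- tibble::tibble(patient_id = ldl$patient_id,
                              grs = ldl$ldl_baseline, n_snps_used = 81L)
  v <- validate_grs(s_perfect, ldl)
  expect_equal(v$r, 1)
  expect_equal(v$r2, 1)
  expect_equal(v$n, 10000)
  # independent score: |r| below the ~2/sqrt(n) null bound
  s_null <- s_perfect |> dplyr::mutate(grs = rnorm(10000))
  v0 <- validate_grs(s_null, ldl)
  expect_lt(abs(v0$r), 0.05)
  expect_equal(v0$r2, v0$r^2)
  expect_error(validate_grs(s_perfect[1:2, ], ldl),
               class = "sepsisldl_validation_error")
})

test_that("VCF dosages count the effect allele, flipping when it is REF", {
  skip_if_not_installed("vcfR")
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t100\trsA\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1",
    "1\t200\trsB\tC\tT\t.\tPASS\t.\tGT\t0/0\t0|1",
    "1\t300\trsC\tA\tG\t.\tPASS\t.\tGT\t./.\t0/1"
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  w <- tibble::tibble(rsid = c("rsA", "rsB", "rsC", "rsD"),
                      effect_allele = c("G", "C", "G", "A"),
                      beta = c(0.1, 0.2, 0.3, 0.4),
                      maf = c(0.2, 0.3, 0.4, 0.1))
  expect_warning(d <- read_vcf_dosages(path, w), "rsD")
  expect_equal(d$rsA, c(1, 2))          # effect allele is ALT
  expect_equal(d$rsB, c(2, 1))          # effect allele is REF: flipped
  expect_equal(d$rsC, c(NA_real_, 1))   # missing genotype stays missing
  s <- compute_grs(d, w[1:3, ])
  expect_equal(s$grs[2], 0.1 * 2 + 0.2 * 1 + 0.3 * 1)
})
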