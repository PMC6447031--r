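#' Read a SNP-weight table
#'
#' Expects a CSV with columns `rsid`, `effect_allele`, `beta` (mg/dL per
#' effect allele) and `maf` (minor/effect allele frequency in (0, 0.5]).
#'
#' @param path CSV file path.
#' @return A tibble of SNP weights.
#' @export
read_snp_weights <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("SNP weight file not found: ", path), class = "sepsisldl_load_error")
  }
  w <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("rsid", "effect_allele", "beta", "maf"), names(w))
  if (length(miss) > 0) {
    abort(paste0("SNP weight table missing column(s): ", paste(miss, collapse = ", ")),
          class = "sepsisldl_load_error")
  }
  if (anyDuplicated(w$rsid)) {
    abort("duplicate rsid in SNP weight table", class = "sepsisldl_load_error")
  }
  if (any(!is.finite(w$beta))) {
    abort("non-finite beta in SNP weight table", class = "sepsisldl_load_error")
  }
  w
}

#' Read a genotype dosage matrix from CSV
#'
#' A dosage table has a `patient_id` column plus one numeric column per SNP
#' (effect-allele counts in \[0, 2\], `NA` for missing).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_dosage_matrix <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"patient_id" %in% names(x)) {
    abort("dosage matrix must have a patient_id column", class = "sepsisldl_load_error")
  }
  x |> mutate(patient_id = as.character(.data$patient_id))
}

#' Read effect-allele dosages from a VCF
#'
#' Extracts per-sample dosages for the SNPs in a weight table from a VCF with
#' GT genotypes, counting copies of the weight table's effect allele.  When
#' the effect allele equals the VCF REF allele the ALT count is flipped
#' (`2 - d`).  SNPs absent from the VCF, or whose alleles do not match the
#' effect allele, are skipped with a warning.  Requires the `vcfR` package.
#'
#' @param path VCF file path.
#' @param weights A SNP-weight table ([read_snp_weights()]).
#' @return A dosage tibble (`patient_id` + one column per matched SNP).
#' @export
read_vcf_dosages <- function(path, weights) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_vcf_dosages requires the vcfR package", class = "sepsisldl_load_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- fix$ID
  out <- list(patient_id = colnames(gt))
  for (i in seq_len(nrow(weights))) {
    rsid <- weights$rsid[i]
    ea <- weights$effect_allele[i]
    j <- match(rsid, ids)
    if (is.na(j)) {
      warn(paste0("SNP not in VCF, skipped: ", rsid))
      next
    }
    alt_count <- vapply(strsplit(gsub("\\|", "/", gt[j, ]), "/", fixed = TRUE),
                        function(a) {
                          if (length(a) == 0 || anyNA(a) || any(a == ".")) {
                            return(NA_real_)
                          }
                          sum(a != "0")
                        }, numeric(1), USE.NAMES = FALSE)
    if (identical(ea, fix$ALT[j])) {
      out[[rsid]] <- alt_count
    } else if (identical(ea, fix$REF[j])) {
      out[[rsid]] <- 2 - alt_count
    } else {
      warn(paste0("effect allele mismatch for ", rsid, ", skipped"))
    }
  }
  as_tibble(out)
}

#' Compute the weighted-allele LDL genetic risk score
#'
#' For each patient, the score is the sum over SNPs of the effect-size weight
#' times the effect-allele dosage (0, 1 or 2).  Missing dosages are imputed
#' at their Hardy-Weinberg expectation `2 * maf`; SNPs in the weight table
#' but absent from the dosage matrix are skipped with a warning and recorded
#' in the `skipped_snps` attribute.
#'
#' @param dosages Dosage tibble (`patient_id` + one column per SNP) or a
#'   numeric matrix with rsid column names.
#' @param weights SNP-weight table.
#' @return A tibble: `patient_id`, `grs`, `n_snps_used` (count of
#'   non-missing, non-skipped SNPs).
#' @examples
#' compute_grs(
#'   tibble::tibble(patient_id = "p1", a = 2, b = 1),
#'   tibble::tibble(rsid = c("a", "b"), effect_allele = "A",
#'                  beta = c(0.1, 0.2), maf = c(0.3, 0.25))
#' )$grs  # 0.4
#' @export
compute_grs <- function(dosages, weights) {
  dosages <- as_tibble(dosages)
  stopifnot("patient_id" %in% names(dosages))
  present <- intersect(weights$rsid, names(dosages))
  skipped <- setdiff(weights$rsid, present)
  if (length(skipped) > 0) {
    warn(paste0(length(skipped), " SNP(s) in weights absent from genotypes, skipped: ",
                paste(head(skipped, 5), collapse = ", ")))
  }
  w <- weights[match(present, weights$rsid), ]
  d <- as.matrix(dosages[, present, drop = FALSE])
  if (length(present) > 0 && nrow(d) > 0 && any(!is.na(d)) &&
      (min(d, na.rm = TRUE) < 0 || max(d, na.rm = TRUE) > 2)) {
    abort("dosages must lie in [0, 2]", class = "sepsisldl_param_error")
  }
  n_used <- rowSums(!is.na(d))
  if (anyNA(d)) {
    imp <- matrix(rep(2 * w$maf, each = nrow(d)), nrow = nrow(d))
    d[is.na(d)] <- imp[is.na(d)]
  }
  grs <- as.numeric(d %*% w$beta)
  out <- tibble(patient_id = dosages$patient_id, grs = grs,
                n_snps_used = as.integer(n_used))
  attr(out, "skipped_snps") <- skipped
  out
}

#' Validate the genetic score against measured LDL
#'
#' Pearson correlation (and its square, the variance explained) between the
#' genetic score and measured baseline LDL on the overlapping patients.
#'
#' @param scores Output of [compute_grs()].
#' @param measured_ldl Tibble with `patient_id` and a measured-LDL column
#'   (`ldl_baseline`, or the first non-id numeric column).
#' @return A list: `r`, `r2`, `n`.
#' @export
validate_grs <- function(scores, measured_ldl) {
  ldl_col <- setdiff(names(measured_ldl), "patient_id")[1]
  both <- scores |>
    inner_join(measured_ldl |> select("patient_id", ldl = all_of(ldl_col)),
               by = "patient_id") |>
    filter(!is.na(.data$grs), !is.na(.data$ldl))
  if (nrow(both) < 3) {
    abort("fewer than 3 overlapping patients between scores and measured LDL",
          class = "sepsisldl_validation_error")
  }
  r <- cor(both$grs, both$ldl)
  list(r = r, r2 = r^2, n = nrow(both))
}
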