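#' Construct a genotype dataset
#'
#' Container for effect-allele dosages over a panel of biallelic SNPs, the
#' central input of every scan in this package. Dosages are alt-allele doses
#' in `[0, 2]` (`NA` marks missing genotypes) and each SNP carries an
#' imputation quality `imputation_r2` in `[0, 1]` (taken as 1 when the source
#' file reports none).
#'
#' @param snps A tibble with columns `snp_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, and optionally `imputation_r2`.
#' @param dosages Numeric matrix, samples in rows and SNPs in columns, with
#'   `rownames` = sample ids and `colnames` = `snps$snp_id`.
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `snps` (tibble, sorted by chromosome and position) and `dosages`.
#' @export
genotype_dataset <- function(snps, dosages) {
  snps <- tibble::as_tibble(snps)
  required <- c("snp_id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols) > 0) {
    abort(paste0("snps is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"imputation_r2" %in% names(snps)) snps$imputation_r2 <- 1
  if (anyNA(snps$imputation_r2)) {
    snps$imputation_r2[is.na(snps$imputation_r2)] <- 1
  }
  if (any(snps$imputation_r2 < 0 | snps$imputation_r2 > 1)) {
    abort("imputation_r2 must lie in [0, 1]")
  }
  key <- paste(snps$chrom, snps$pos, snps$ref, snps$alt)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate site(s): ", paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  if (anyDuplicated(snps$snp_id)) abort("duplicate snp_id")
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(snps)) {
    abort("ncol(dosages) must equal nrow(snps)")
  }
  if (is.null(colnames(dosages))) colnames(dosages) <- snps$snp_id
  if (!identical(colnames(dosages), snps$snp_id)) {
    dosages <- dosages[, snps$snp_id, drop = FALSE]
  }
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < -1e-9 || rng[2] > 2 + 1e-9)) {
    abort("dosages must lie in [0, 2]")
  }
  # canonical order: numeric-aware chromosome sort, then position
  ord <- order(chrom_rank(snps$chrom), snps$pos)
  snps <- snps[ord, ]
  dosages <- dosages[, ord, drop = FALSE]
  structure(list(snps = snps, dosages = dosages), class = "genotype_dataset")
}

chrom_rank <- function(chrom) {
  ch <- sub("^chr", "", as.character(chrom))
  num <- suppressWarnings(as.numeric(ch))
  num[is.na(num)] <- 1e6 + as.numeric(factor(ch[is.na(num)]))
  num
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf(
    "<genotype_dataset> %d samples x %d SNPs (%s missing)\n",
    nrow(x$dosages), nrow(x$snps),
    format(mean(is.na(x$dosages)), digits = 3)
  ))
  print(head(x$snps, 5))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$dosages)

sample_ids <- function(dataset) rownames(dataset$dosages)

#' Alt-allele frequency per SNP
#'
#' Frequencies are estimated as mean dosage / 2, ignoring missing genotypes.
#'
#' @param dataset A [genotype_dataset()].
#' @param samples Optional character vector of sample ids to restrict to.
#' @return Named numeric vector of alt-allele frequencies.
#' @export
alt_frequency <- function(dataset, samples = NULL) {
  d <- dataset$dosages
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  colMeans(d, na.rm = TRUE) / 2
}

#' Build a sample table
#'
#' @param sample_id Character vector of unique ids.
#' @param date_bp Numeric, years before present (>= 0).
#' @param cohort Optional cohort label; defaults to `"modern"` for
#'   `date_bp == 0` and `"ancient"` otherwise.
#' @return A tibble with columns `sample_id`, `date_bp`, `cohort`.
#' @export
sample_table <- function(sample_id, date_bp, cohort = NULL) {
  if (anyDuplicated(sample_id)) abort("sample ids must be unique")
  if (any(date_bp < 0)) abort("date_bp must be >= 0")
  if (is.null(cohort)) cohort <- ifelse(date_bp == 0, "modern", "ancient")
  tibble::tibble(sample_id = as.character(sample_id),
                 date_bp = as.numeric(date_bp),
                 cohort = as.character(cohort))
}
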