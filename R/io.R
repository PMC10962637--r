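#' Read genotypes from VCF or dosage TSV
#'
#' VCF parsing is delegated to \pkg{vcfR}. Dosages are taken from the `DS`
#' FORMAT field when present, otherwise from `GT` as the alt-allele count;
#' missing genotypes stay missing (`NA`) and are never imputed here. Per-SNP
#' imputation quality is read from the `R2` INFO key (1.0 when absent).
#'
#' @param path Path to a `.vcf` file or a dosage TSV written by
#'   [write_genotypes()].
#' @param site_filter Optional: a character vector of SNP ids to keep, or a
#'   data frame with columns `chrom`, `start`, `end` defining regions.
#' @return A [genotype_dataset()].
#' @export
load_genotypes <- function(path, site_filter = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ds <- if (grepl("\\.vcf(\\.gz)?$", path)) {
    load_genotypes_vcf(path)
  } else {
    load_genotypes_tsv(path)
  }
  if (!is.null(site_filter)) {
    keep <- if (is.character(site_filter)) {
      ds$snps$snp_id %in% site_filter
    } else {
      sf <- tibble::as_tibble(site_filter)
      purrr::map_lgl(seq_len(nrow(ds$snps)), function(i) {
        any(sf$chrom == ds$snps$chrom[i] &
              sf$start <= ds$snps$pos[i] & ds$snps$pos[i] <= sf$end)
      })
    }
    ds <- genotype_dataset(ds$snps[keep, ], ds$dosages[, keep, drop = FALSE])
  }
  ds
}

load_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  snp_id <- fix[, "ID"]
  no_id <- is.na(snp_id) | snp_id == "."
  snp_id[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  r2 <- suppressWarnings(vcfR::extract.info(v, "R2", as.numeric = TRUE))
  if (is.null(r2) || all(is.na(r2))) r2 <- rep(1, nrow(fix))
  r2[is.na(r2)] <- 1
  snps <- tibble::tibble(
    snp_id = snp_id,
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    imputation_r2 = r2
  )
  fmt <- v@gt[, 1]
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    dose <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    dose <- apply(gt, 2, function(col) {
      alleles <- strsplit(gsub("\\|", "/", col), "/", fixed = TRUE)
      vapply(alleles, function(a) {
        if (length(a) == 0 || anyNA(a) || any(a == ".")) return(NA_real_)
        sum(a != "0")
      }, numeric(1))
    })
    if (is.null(dim(dose))) dose <- matrix(dose, nrow = nrow(snps))
  }
  rownames(dose) <- snps$snp_id
  genotype_dataset(snps, t(dose))
}

load_genotypes_tsv <- function(path) {
  # read numerics as text, then convert via as.numeric (strtod), so
  # full-precision dosages round-trip exactly
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA", "."),
                         col_types = readr::cols(.default = "c"))
  meta <- c("snp_id", "chrom", "pos", "ref", "alt", "imputation_r2")
  if (!all(meta %in% names(tab))) {
    abort("dosage TSV must have columns snp_id, chrom, pos, ref, alt, imputation_r2")
  }
  tab$pos <- as.integer(tab$pos)
  tab$imputation_r2 <- as.numeric(tab$imputation_r2)
  sample_cols <- setdiff(names(tab), meta)
  dos <- t(vapply(tab[sample_cols], as.numeric, numeric(nrow(tab))))
  if (nrow(tab) == 1) dos <- matrix(dos, ncol = 1,
                                    dimnames = list(sample_cols, NULL))
  colnames(dos) <- tab$snp_id
  genotype_dataset(tab[, meta], dos)
}

#' Write genotypes as VCF (DS dosages) or dosage TSV
#'
#' The VCF carries dosages in a `DS` FORMAT field and per-SNP imputation
#' quality in an `R2` INFO key. Numeric values are printed at full precision
#' so a write/read round-trip reproduces the dosage matrix exactly.
#'
#' @param dataset A [genotype_dataset()].
#' @param path Output path; format chosen by extension (`.vcf` vs anything
#'   else = TSV) unless `format` is given.
#' @param format `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(dataset, path,
                            format = if (grepl("\\.vcf$", path)) "vcf" else "tsv") {
  format <- match.arg(format, c("vcf", "tsv"))
  if (format == "vcf") write_genotypes_vcf(dataset, path) else
    write_genotypes_tsv(dataset, path)
  invisible(path)
}

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "."
  out
}

write_genotypes_vcf <- function(dataset, path) {
  snps <- dataset$snps
  dos <- dataset$dosages
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality r-squared\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alt-allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dos)), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(snps)), function(i) {
    paste(c(snps$chrom[i], snps$pos[i], snps$snp_id[i], snps$ref[i],
            snps$alt[i], ".", "PASS",
            paste0("R2=", fmt_num(snps$imputation_r2[i])), "DS",
            fmt_num(dos[, i])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
}

write_genotypes_tsv <- function(dataset, path) {
  tab <- dataset$snps[, c("snp_id", "chrom", "pos", "ref", "alt", "imputation_r2")]
  # full-precision text so the dosage matrix round-trips exactly
  tab$imputation_r2 <- fmt_num(tab$imputation_r2)
  dmat <- t(dataset$dosages)
  dchr <- tibble::as_tibble(matrix(fmt_num(dmat), nrow = nrow(dmat),
                                   dimnames = dimnames(dmat)))
  tab <- dplyr::bind_cols(tab, dchr)
  readr::write_tsv(tab, path, na = ".", progress = FALSE)
}

#' Read / write a dated sample table
#'
#' @param path TSV with columns `sample_id`, `date_bp`, `cohort`.
#' @return A [sample_table()] tibble.
#' @export
load_samples <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  sample_table(tab$sample_id, tab$date_bp,
               cohort = if ("cohort" %in% names(tab)) tab$cohort else NULL)
}

#' @rdname load_samples
#' @param samples A [sample_table()].
#' @export
write_samples <- function(samples, path) {
  readr::write_tsv(samples, path, progress = FALSE)
  invisible(path)
}

#' Read / write per-SNP selection score tables (SDS / iHS)
#'
#' @param path TSV with columns `snp_id`, `allele`, `score`.
#' @return Tibble `snp_id`, `allele`, `score`.
#' @export
load_scores <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("snp_id", "score") %in% names(tab))) {
    abort("score TSV needs columns snp_id and score")
  }
  if (!"allele" %in% names(tab)) tab$allele <- NA_character_
  if (any(!is.finite(tab$score))) abort("scores must be finite")
  tab[, c("snp_id", "allele", "score")]
}

#' @rdname load_scores
#' @param scores Tibble `snp_id`, `allele`, `score`.
#' @export
write_scores <- function(scores, path) {
  readr::write_tsv(scores, path, progress = FALSE)
  invisible(path)
}
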