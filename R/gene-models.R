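#' Assemble gene expression weight models, keeping one tissue per gene
#'
#' Combines a long weight table with a per-gene/tissue training summary.
#' When a gene has models in several tissues and `best_tissue = TRUE`
#' (default), exactly the model with maximal training R-squared is retained;
#' ties are broken deterministically by the lexicographically smallest
#' tissue name.
#'
#' @param weights Tibble with columns `gene_id`, `snp_id`, `effect_allele`,
#'   `other_allele`, `weight`, and (for multi-tissue tables) `tissue`.
#' @param summary Tibble with columns `gene_id`, `tissue`, `training_r2`.
#' @param best_tissue Keep only the best-trained tissue per gene?
#' @return A tibble of class `gene_models`: one row per (gene, SNP) with
#'   `gene_id`, `tissue`, `training_r2`, `snp_id`, `effect_allele`,
#'   `other_allele`, `weight`.
#' @export
gene_models <- function(weights, summary, best_tissue = TRUE) {
  weights <- tibble::as_tibble(weights)
  summary <- tibble::as_tibble(summary)
  names(weights)[names(weights) == "gene"] <- "gene_id"
  names(summary)[names(summary) == "gene"] <- "gene_id"
  req_w <- c("gene_id", "snp_id", "effect_allele", "other_allele", "weight")
  if (!all(req_w %in% names(weights))) {
    abort(paste0("weights needs columns: ", paste(req_w, collapse = ", ")))
  }
  if (!all(c("gene_id", "tissue", "training_r2") %in% names(summary))) {
    abort("summary needs columns gene_id, tissue, training_r2")
  }
  if (any(summary$training_r2 < 0)) abort("negative training_r2")
  if (!"tissue" %in% names(weights)) {
    if (anyDuplicated(summary$gene_id)) {
      abort("weights lack a tissue column but summary has multiple tissues per gene")
    }
    weights <- dplyr::left_join(weights, summary[, c("gene_id", "tissue")],
                                by = "gene_id")
  }
  missing_genes <- setdiff(weights$gene_id, summary$gene_id)
  if (length(missing_genes) > 0) {
    abort(paste0("gene(s) in weights absent from summary: ",
                 paste(head(missing_genes, 5), collapse = ", ")))
  }
  if (any(!is.finite(weights$weight))) abort("weights must be finite")

  keep <- summary
  if (best_tissue) {
    keep <- summary |>
      dplyr::arrange(.data$gene_id, dplyr::desc(.data$training_r2),
                     .data$tissue) |>
      dplyr::distinct(.data$gene_id, .keep_all = TRUE)
  }
  out <- dplyr::inner_join(weights, keep, by = c("gene_id", "tissue"))

  empty <- setdiff(keep$gene_id, out$gene_id)
  if (length(empty) > 0) {
    warn(paste0("dropping ", length(empty), " gene(s) with no variants"))
  }
  out <- out[, c("gene_id", "tissue", "training_r2", "snp_id",
                 "effect_allele", "other_allele", "weight")]
  class(out) <- c("gene_models", class(out))
  out
}

#' Load gene models from PredictDB-style TSV files
#'
#' @param weights_path TSV with columns `gene` (or `gene_id`), `snp_id`,
#'   `effect_allele`, `other_allele`, `weight`, optionally `tissue`.
#' @param summary_path TSV with columns `gene` (or `gene_id`), `tissue`,
#'   `training_r2`.
#' @inheritParams gene_models
#' @return A `gene_models` tibble (see [gene_models()]).
#' @export
load_gene_models <- function(weights_path, summary_path, best_tissue = TRUE) {
  w <- readr::read_tsv(weights_path, show_col_types = FALSE, progress = FALSE)
  s <- readr::read_tsv(summary_path, show_col_types = FALSE, progress = FALSE)
  gene_models(w, s, best_tissue = best_tissue)
}

#' @rdname load_gene_models
#' @param models A `gene_models` tibble.
#' @export
write_gene_models <- function(models, weights_path, summary_path) {
  w <- models[, c("gene_id", "tissue", "snp_id", "effect_allele",
                  "other_allele", "weight")]
  names(w)[1] <- "gene"
  readr::write_tsv(w, weights_path, progress = FALSE)
  s <- dplyr::distinct(models[, c("gene_id", "tissue", "training_r2")])
  names(s)[1] <- "gene"
  readr::write_tsv(s, summary_path, progress = FALSE)
  invisible(weights_path)
}

#' Per-gene model summary
#'
#' @param models A `gene_models` tibble.
#' @return Tibble with one row per gene: `gene_id`, `tissue`, `training_r2`,
#'   `n_snps`.
#' @export
model_summary <- function(models) {
  models |>
    dplyr::group_by(.data$gene_id, .data$tissue, .data$training_r2) |>
    dplyr::summarise(n_snps = dplyr::n(), .groups = "drop")
}

strand_ambiguous <- function(a1, a2) {
  paste0(a1, a2) %in% c("AT", "TA", "CG", "GC")
}

#' Orient model effect alleles against a genotype dataset
#'
#' Each model variant is matched to the dataset by SNP id. If the effect
#' allele equals the dataset's alt allele the dosage is used as-is; if it
#' equals the ref allele the orientation is flipped (dose replaced by
#' `2 - dose` downstream); if it matches neither, the variant is flagged
#' unresolvable and contributes nothing to predictions. Strand-ambiguous
#' A/T and C/G sites are resolved by allele match only (no frequency
#' heuristic) and flagged.
#'
#' @param models A `gene_models` tibble.
#' @param dataset A [genotype_dataset()].
#' @param quiet Suppress the per-call orientation message?
#' @return `models` with added columns `in_dataset`, `flip`, `resolvable`,
#'   `ambiguous`, `imputation_r2`.
#' @export
align_alleles <- function(models, dataset, quiet = FALSE) {
  snps <- dataset$snps[, c("snp_id", "ref", "alt", "imputation_r2")]
  out <- dplyr::left_join(tibble::as_tibble(models), snps, by = "snp_id")
  out$in_dataset <- !is.na(out$ref)
  out$flip <- out$in_dataset & out$effect_allele == out$ref
  out$resolvable <- out$in_dataset &
    (out$effect_allele == out$alt | out$effect_allele == out$ref)
  out$ambiguous <- out$resolvable & strand_ambiguous(out$ref, out$alt)
  if (!quiet) {
    n_unres <- sum(out$in_dataset & !out$resolvable)
    n_amb <- sum(out$ambiguous)
    if (n_unres > 0 || n_amb > 0) {
      message(sprintf(
        "align_alleles: %d unresolvable variant(s), %d strand-ambiguous site(s) resolved by allele match",
        n_unres, n_amb))
    }
  }
  out$ref <- NULL
  out$alt <- NULL
  class(out) <- c("gene_models", class(out))
  out
}

#' Oriented effect-allele dosage matrix for one aligned model
#'
#' @param aligned One gene's rows of an [align_alleles()] result.
#' @param dataset A [genotype_dataset()].
#' @return Samples x variants matrix of effect-allele dosages (flipped
#'   variants become `2 - dose`); unresolvable variants are omitted.
#' @export
oriented_dosages <- function(aligned, dataset) {
  use <- aligned[aligned$resolvable, ]
  d <- dataset$dosages[, use$snp_id, drop = FALSE]
  flip_cols <- which(use$flip)
  if (length(flip_cols) > 0) {
    d[, flip_cols] <- 2 - d[, flip_cols, drop = FALSE]
  }
  d
}
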