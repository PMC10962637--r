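#' Predict normalized expression from genotype dosages
#'
#' For each gene the prediction is the weighted sum `sum_i beta_i * dose_i`
#' of oriented effect-allele dosages over the model's resolvable variants
#' (in expression-SD units). Variants absent from the dataset or with an
#' unresolvable effect allele contribute nothing and reduce the gene's
#' coverage (the fraction of total model weight `|beta|` attached to
#' resolvable SNPs). A sample's missing dosage is replaced by twice the
#' cohort-wide alt-allele frequency of that SNP.
#'
#' @param dataset A [genotype_dataset()].
#' @param models A `gene_models` tibble (see [gene_models()]), aligned or
#'   not; alignment is performed internally when needed.
#' @return An object of class `predicted_expression`: list with
#'   `expression` (genes x samples matrix), `coverage` (tibble `gene_id`,
#'   `coverage`), and `unpredictable` (gene ids with zero coverage, which
#'   are excluded from the matrix).
#' @export
predict_expression <- function(dataset, models) {
  aligned <- if ("resolvable" %in% names(models)) models else
    align_alleles(models, dataset, quiet = TRUE)
  D <- dataset$dosages
  # fill missing doses with 2 * cohort-wide alt-allele frequency
  if (anyNA(D)) {
    fill <- 2 * alt_frequency(dataset)
    na_idx <- which(is.na(D), arr.ind = TRUE)
    D[na_idx] <- fill[na_idx[, 2]]
  }
  cov_tbl <- aligned |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      coverage = {
        tot <- sum(abs(.data$weight))
        # an all-zero-weight model predicts 0 everywhere; coverage falls
        # back to the fraction of resolvable variants
        if (tot == 0) mean(.data$resolvable)
        else sum(abs(.data$weight[.data$resolvable])) / tot
      },
      .groups = "drop"
    )
  unpredictable <- cov_tbl$gene_id[cov_tbl$coverage == 0]
  genes <- setdiff(unique(aligned$gene_id), unpredictable)
  use <- aligned[aligned$resolvable & aligned$gene_id %in% genes, ]
  # one pass per gene: signed weights absorb orientation flips,
  # beta * (2 - dose) = 2*beta - beta*dose
  split_rows <- split(seq_len(nrow(use)), use$gene_id)
  expr <- matrix(0, nrow = length(genes), ncol = nrow(D),
                 dimnames = list(genes, rownames(D)))
  for (g in names(split_rows)) {
    rows <- split_rows[[g]]
    w <- use$weight[rows]
    flip <- use$flip[rows]
    w_signed <- ifelse(flip, -w, w)
    offset <- 2 * sum(w[flip])
    expr[g, ] <- D[, use$snp_id[rows], drop = FALSE] %*% w_signed + offset
  }
  if (length(unpredictable) > 0) {
    warn(paste0(length(unpredictable),
                " gene(s) unpredictable (zero coverage), excluded"))
  }
  structure(list(expression = expr, coverage = cov_tbl,
                 unpredictable = unpredictable),
            class = "predicted_expression")
}

#' @export
print.predicted_expression <- function(x, ...) {
  cat(sprintf("<predicted_expression> %d genes x %d samples\n",
              nrow(x$expression), ncol(x$expression)))
  invisible(x)
}

#' Gene-level imputation quality
#'
#' The gene's quality is the `|beta|`-weighted average of its member SNPs'
#' imputation quality scores:
#' `r2_gene = sum(|beta_i| * r2_i) / sum(|beta_i|)`, over resolvable
#' variants.
#'
#' @param models A `gene_models` tibble.
#' @param dataset A [genotype_dataset()] supplying per-SNP `imputation_r2`.
#' @return Tibble `gene_id`, `r2_gene`.
#' @export
gene_quality <- function(models, dataset) {
  aligned <- if ("resolvable" %in% names(models)) models else
    align_alleles(models, dataset, quiet = TRUE)
  use <- aligned[aligned$resolvable, ]
  no_resolvable <- setdiff(unique(aligned$gene_id), unique(use$gene_id))
  if (length(no_resolvable) > 0) {
    warn(paste0(length(no_resolvable),
                " gene(s) with no resolvable variants dropped from quality"))
  }
  out <- use |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      wsum = sum(abs(.data$weight)),
      r2_gene = sum(abs(.data$weight) * .data$imputation_r2),
      .groups = "drop"
    )
  if (any(out$wsum == 0)) {
    abort(paste0("degenerate model (all zero weights): ",
                 paste(out$gene_id[out$wsum == 0], collapse = ", ")))
  }
  out$r2_gene <- out$r2_gene / out$wsum
  out[, c("gene_id", "r2_gene")]
}

#' Drop the lowest-quality fraction of genes
#'
#' Removes genes whose `r2_gene` falls strictly below the empirical
#' `drop_fraction` quantile of the input qualities (the order statistic at
#' rank `floor(drop_fraction * n) + 1`); genes tied with the threshold are
#' retained.
#'
#' @param qualities Tibble `gene_id`, `r2_gene` (from [gene_quality()]).
#' @param drop_fraction Fraction of genes to drop, in `[0, 1)`.
#' @return List with `retained` (character gene ids, input order),
#'   `threshold` (the quantile used) and `n_dropped`.
#' @export
filter_by_quality <- function(qualities, drop_fraction = 0.20) {
  if (nrow(qualities) == 0) abort("no gene qualities supplied")
  if (drop_fraction < 0 || drop_fraction >= 1) {
    abort("drop_fraction must lie in [0, 1)")
  }
  x <- sort(qualities$r2_gene)
  k <- floor(drop_fraction * length(x)) + 1
  threshold <- x[k]
  keep <- qualities$r2_gene >= threshold
  list(
    retained = qualities$gene_id[keep],
    threshold = threshold,
    n_dropped = sum(!keep)
  )
}

#' Write a predicted-expression table
#'
#' One row per gene: model metadata, gene quality, coverage, then one
#' column per sample.
#'
#' @param pred A [predict_expression()] result.
#' @param models The `gene_models` tibble used for prediction.
#' @param qualities Optional [gene_quality()] tibble.
#' @param path Output TSV path.
#' @export
write_predicted_expression <- function(pred, models, path, qualities = NULL) {
  meta <- dplyr::distinct(
    tibble::as_tibble(models)[, c("gene_id", "tissue", "training_r2")])
  tab <- tibble::tibble(gene_id = rownames(pred$expression)) |>
    dplyr::left_join(meta, by = "gene_id") |>
    dplyr::left_join(pred$coverage, by = "gene_id")
  if (!is.null(qualities)) {
    tab <- dplyr::left_join(tab, qualities, by = "gene_id")
  }
  tab <- dplyr::bind_cols(tab, tibble::as_tibble(pred$expression))
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}
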