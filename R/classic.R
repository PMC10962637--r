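#' Gene-level selection scores from SNP-level SDS/iHS
#'
#' Combines per-SNP normalized selection scores with a gene's eQTL weights:
#' `z = sum(beta_i * score_i) / sqrt(sum(beta_i^2))`. Scores are first
#' polarized so the sign refers to the model's effect allele: a score
#' reported for the non-effect allele is negated; a score whose allele
#' matches neither model allele is treated as unavailable; a score with no
#' allele tag is assumed to already refer to the effect allele. Because the
#' SNP scores are standard normal under neutrality, `z` is too.
#'
#' @param models A `gene_models` tibble (see [gene_models()]).
#' @param scores Tibble `snp_id`, `allele`, `score` (normalized SDS or
#'   iHS).
#' @param denominator `"scored"` (default) sums `beta^2` over scored SNPs
#'   only, preserving the standard-normal null after masking; `"all"` sums
#'   over every model SNP.
#' @return Tibble `gene_id`, `z`, `n_snps`, `n_scored`, `frac_scored`.
#'   Genes with no scored SNPs, or zero weight norm over scored SNPs, get
#'   `NA` z (excluded downstream).
#' @export
gene_level_scores <- function(models, scores,
                              denominator = c("scored", "all")) {
  denominator <- match.arg(denominator)
  m <- tibble::as_tibble(models)
  if (nrow(m) == 0) abort("empty model table")
  sc <- tibble::as_tibble(scores)
  joined <- dplyr::left_join(m, sc, by = "snp_id",
                             relationship = "many-to-one")
  polarity <- dplyr::case_when(
    is.na(joined$score) ~ NA_real_,
    is.na(joined$allele) ~ 1,
    joined$allele == joined$effect_allele ~ 1,
    joined$allele == joined$other_allele ~ -1,
    TRUE ~ NA_real_
  )
  joined$polarized <- joined$score * polarity
  joined |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_snps = dplyr::n(),
      n_scored = sum(!is.na(.data$polarized)),
      num = sum(.data$weight * .data$polarized, na.rm = TRUE),
      den = if (denominator == "scored") {
        sqrt(sum(.data$weight[!is.na(.data$polarized)]^2))
      } else {
        sqrt(sum(.data$weight^2))
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      z = dplyr::if_else(.data$n_scored > 0 & .data$den > 0,
                         .data$num / .data$den, NA_real_),
      frac_scored = .data$n_scored / .data$n_snps
    ) |>
    dplyr::select("gene_id", "z", "n_snps", "n_scored", "frac_scored")
}

#' Half-missing filter for gene-level scores
#'
#' Removes genes for which fewer than half of the model SNPs have scores
#' (strict `frac_scored < 0.5`; exactly half is retained), plus genes whose
#' z is undefined.
#'
#' @param gene_scores A [gene_level_scores()] tibble.
#' @param min_frac Minimum scored fraction (default 0.5).
#' @return The retained rows.
#' @export
missing_filter <- function(gene_scores, min_frac = 0.5) {
  gene_scores[!is.na(gene_scores$z) & gene_scores$frac_scored >= min_frac, ]
}

#' P-values for gene-level Z-scores, with genomic control
#'
#' The normalized gene-level statistics are treated as Z-scores: two-sided
#' normal p-values, then genomic control on `z^2` (exactly as in the
#' expression scan) to absorb residual correlation between model SNPs,
#' and BH FDR calling.
#'
#' @param gene_scores A [gene_level_scores()] tibble (after
#'   [missing_filter()]), or a bare numeric z vector.
#' @param q FDR level.
#' @return Tibble with added `p_raw`, `p_gc`, `q_value`, `significant`;
#'   attributes `lambda`, `lambda_raw`.
#' @export
score_pvalues <- function(gene_scores, q = 0.05) {
  if (is.numeric(gene_scores)) {
    gene_scores <- tibble::tibble(gene_id = as.character(seq_along(gene_scores)),
                                  z = gene_scores)
  }
  z <- gene_scores$z
  p_raw <- pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
  gc <- genomic_control(z^2)
  fdr <- fdr_call(gc$p_gc, q = q)
  out <- gene_scores
  out$p_raw <- p_raw
  out$p_gc <- gc$p_gc
  out$q_value <- fdr$q_values
  out$significant <- fdr$significant
  attr(out, "lambda") <- gc$lambda
  attr(out, "lambda_raw") <- gc$lambda_raw
  class(out) <- c("gene_score_result", class(out))
  out
}

#' @exportS3Method generics::glance
glance.gene_score_result <- function(x, ...) {
  tibble::tibble(
    lambda = attr(x, "lambda"),
    lambda_raw = attr(x, "lambda_raw"),
    n_tests = nrow(x),
    n_significant = sum(x$significant)
  )
}

#' Concordance between the expression scan and gene-level classic scores
#'
#' Over genes present in both result sets: how many are significant in
#' both; among expression-scan-significant genes with scores, how many
#' agree in predicted direction (sign of the time slope vs sign of z); and
#' the Spearman rank correlation between slope and z over all shared
#' genes.
#'
#' @param twss A `twss_result` (needs `gene_id`, `beta`, `significant`).
#' @param gene_scores A [score_pvalues()] result (needs `gene_id`, `z`,
#'   `significant`).
#' @return One-row tibble: `n_shared`, `n_jointly_significant`,
#'   `n_twss_significant_scored`, `n_sign_agree`, `spearman_rho`.
#' @export
concordance <- function(twss, gene_scores) {
  shared <- dplyr::inner_join(
    tibble::as_tibble(twss)[, c("gene_id", "beta", "significant")],
    tibble::as_tibble(gene_scores)[, c("gene_id", "z", "significant")],
    by = "gene_id", suffix = c("_twss", "_score"))
  if (nrow(shared) == 0) abort("no shared genes between the two result sets")
  sig_t <- shared[shared$significant_twss, ]
  tibble::tibble(
    n_shared = nrow(shared),
    n_jointly_significant = sum(shared$significant_twss &
                                  shared$significant_score),
    n_twss_significant_scored = nrow(sig_t),
    n_sign_agree = sum(sign(sig_t$beta) == sign(sig_t$z)),
    spearman_rho = cor(shared$beta, shared$z, method = "spearman")
  )
}

#' Run the gene-level classic-statistic analysis
#'
#' Chains [gene_level_scores()], [missing_filter()], [score_pvalues()] and,
#' when a `twss_result` is supplied, [concordance()].
#'
#' @inheritParams gene_level_scores
#' @inheritParams score_pvalues
#' @param twss Optional `twss_result` for the concordance report.
#' @return List of class `classic_result`: `scores` (per-gene result
#'   tibble), `concordance` (or `NULL`).
#' @export
run_classic <- function(models, scores, twss = NULL, q = 0.05,
                        denominator = "scored") {
  gs <- gene_level_scores(models, scores, denominator = denominator)
  gs <- missing_filter(gs)
  if (nrow(gs) < 2) abort("fewer than 2 genes survive the half-missing filter")
  res <- score_pvalues(gs, q = q)
  conc <- if (!is.null(twss)) concordance(twss, res) else NULL
  structure(list(scores = res, concordance = conc), class = "classic_result")
}

#' @export
print.classic_result <- function(x, ...) {
  cat(sprintf("<classic_result> %d genes, lambda = %.3f, %d significant\n",
              nrow(x$scores), attr(x$scores, "lambda"),
              sum(x$scores$significant)))
  if (!is.null(x$concordance)) print(x$concordance)
  invisible(x)
}

#' Expression-scan slope versus gene-level classic score
#'
#' Scatter of the per-gene time slope against the gene-level z, colored by
#' which analysis (if either) calls the gene significant.
#'
#' @param twss A `twss_result`.
#' @param gene_scores A [score_pvalues()] result.
#' @return A ggplot.
#' @export
plot_concordance <- function(twss, gene_scores) {
  shared <- dplyr::inner_join(
    tibble::as_tibble(twss)[, c("gene_id", "beta", "significant")],
    tibble::as_tibble(gene_scores)[, c("gene_id", "z", "significant")],
    by = "gene_id", suffix = c("_twss", "_score"))
  shared$class <- dplyr::case_when(
    shared$significant_twss & shared$significant_score ~ "both",
    shared$significant_twss ~ "expression scan",
    shared$significant_score ~ "gene-level score",
    TRUE ~ "neither"
  )
  ggplot2::ggplot(shared, ggplot2::aes(.data$beta, .data$z,
                                       color = .data$class)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::scale_color_manual(values = c(
      "both" = "purple", "expression scan" = "steelblue",
      "gene-level score" = "firebrick", "neither" = "grey60")) +
    ggplot2::labs(x = "expression change per year (beta)",
                  y = "gene-level score (z)", color = NULL)
}

#' Write the gene-level score table
#'
#' @param result A [score_pvalues()] result.
#' @param path Output TSV path.
#' @export
write_gene_scores <- function(result, path) {
  readr::write_tsv(tibble::as_tibble(result), path, progress = FALSE)
  invisible(path)
}
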