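#' Pair predicted and observed population expression medians
#'
#' Aligns two gene x population tables of medians -- predicted expression
#' (model units) and observed expression (read-count units) -- to their
#' shared genes and populations.
#'
#' @param predicted,observed Tibbles with a `gene_id` column and one column
#'   per population.
#' @return List of class `population_expression` with matrices `predicted`
#'   and `observed` (genes x populations, identical dimnames).
#' @export
population_expression <- function(predicted, observed) {
  predicted <- tibble::as_tibble(predicted)
  observed <- tibble::as_tibble(observed)
  if (!"gene_id" %in% names(predicted) || !"gene_id" %in% names(observed)) {
    abort("both tables need a gene_id column")
  }
  pops <- intersect(setdiff(names(predicted), "gene_id"),
                    setdiff(names(observed), "gene_id"))
  if (length(pops) < 3) abort("need at least 3 shared populations")
  genes <- intersect(predicted$gene_id, observed$gene_id)
  if (length(genes) == 0) abort("no shared genes")
  to_mat <- function(tab) {
    m <- as.matrix(tab[match(genes, tab$gene_id), pops])
    rownames(m) <- genes
    m
  }
  structure(list(predicted = to_mat(predicted), observed = to_mat(observed)),
            class = "population_expression")
}

#' Per-gene Spearman correlation of population medians
#'
#' For each gene, the rank correlation (average ranks for ties) between the
#' predicted-median and observed-median vectors across populations. Genes
#' with a constant vector in either table have undefined correlation and
#' are skipped with a warning.
#'
#' @param pop_expr A [population_expression()].
#' @return Tibble `gene_id`, `rho` (`NA` for skipped genes).
#' @export
per_gene_spearman <- function(pop_expr) {
  P <- pop_expr$predicted
  O <- pop_expr$observed
  rho <- vapply(seq_len(nrow(P)), function(g) {
    suppressWarnings(cor(P[g, ], O[g, ], method = "spearman"))
  }, numeric(1))
  if (anyNA(rho)) {
    warn(paste0(sum(is.na(rho)),
                " gene(s) with constant medians skipped (undefined rho)"))
  }
  tibble::tibble(gene_id = rownames(P), rho = rho)
}

#' Permutation p-value for predicted/observed agreement
#'
#' The statistic is `T = sum_g rho_g`, the summed per-gene Spearman
#' correlation. The null permutes the assignment of observed-expression
#' gene rows to predicted-expression gene rows, keeping population columns
#' intact so all between-population relationships are preserved. One-sided
#' upper tail with add-one correction:
#' `p = (1 + #\{T_null >= T\}) / (1 + n_perm)`.
#'
#' @param pop_expr A [population_expression()].
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return List of class `concord_result`: `statistic` (T), `p_value`,
#'   `n_perm`, `rhos` (per-gene tibble), `null_statistics`.
#' @export
permutation_pvalue <- function(pop_expr, n_perm = 10000, seed = 1L) {
  if (n_perm < 100) abort("n_perm must be >= 100")
  n_genes <- nrow(pop_expr$predicted)
  if (n_genes < 2) abort("need at least 2 genes")
  rhos <- per_gene_spearman(pop_expr)
  T_obs <- sum(rhos$rho, na.rm = TRUE)
  # rank rows once; any row-to-row pairing's Spearman rho is then the
  # Pearson correlation of the rank rows
  RP <- t(apply(pop_expr$predicted, 1, rank))
  RO <- t(apply(pop_expr$observed, 1, rank))
  C <- suppressWarnings(cor(t(RP), t(RO)))
  set.seed(seed)
  T_null <- vapply(seq_len(n_perm), function(b) {
    perm <- sample(n_genes)
    sum(C[cbind(seq_len(n_genes), perm)], na.rm = TRUE)
  }, numeric(1))
  p <- (1 + sum(T_null >= T_obs)) / (1 + n_perm)
  structure(list(statistic = T_obs, p_value = p, n_perm = n_perm,
                 rhos = rhos, null_statistics = T_null),
            class = "concord_result")
}

#' @export
print.concord_result <- function(x, ...) {
  cat(sprintf("<concord_result> T = %.3f over %d genes, p = %.4g (%d perms)\n",
              x$statistic, nrow(x$rhos), x$p_value, x$n_perm))
  invisible(x)
}

#' Write the concordance report
#'
#' JSON with the summed statistic, p-value and permutation count, plus a
#' per-gene rho TSV alongside.
#'
#' @param result A [permutation_pvalue()] result.
#' @param json_path Output JSON path.
#' @param rho_path Optional per-gene rho TSV path.
#' @export
write_concordance <- function(result, json_path, rho_path = NULL) {
  jsonlite::write_json(
    list(statistic = result$statistic, p_value = result$p_value,
         n_perm = result$n_perm),
    json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(rho_path)) {
    readr::write_tsv(result$rhos, rho_path, progress = FALSE)
  }
  invisible(json_path)
}
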