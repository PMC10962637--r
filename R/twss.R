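#' Regress predicted expression on time for one gene
#'
#' Ordinary least squares of expression on forward time `t = -date_bp`
#' (with intercept), so a positive slope means expression increasing toward
#' the present. The Wald chi-square `(beta/se)^2` is referred to a 1-df
#' chi-square upper tail.
#'
#' @param expr Numeric vector of per-sample predicted expression, in the
#'   order of `samples`.
#' @param samples A [sample_table()] (or a numeric vector of `date_bp`).
#' @return Tibble with `beta` (expression-SD per year), `se`, `chi2_raw`,
#'   `p_raw`.
#' @export
regress_on_time <- function(expr, samples) {
  date_bp <- if (is.numeric(samples)) samples else samples$date_bp
  if (length(expr) != length(date_bp)) abort("expr and dates differ in length")
  ok <- !is.na(expr) & !is.na(date_bp)
  if (sum(ok) < 3) abort("need at least 3 samples")
  if (length(unique(date_bp[ok])) < 2) abort("dates are constant")
  fit <- ols_time(matrix(expr[ok], nrow = 1), -date_bp[ok])
  tibble::tibble(beta = fit$beta, se = fit$se,
                 chi2_raw = fit$chi2, p_raw = fit$p)
}

# Row-wise simple linear regression of Y (genes x samples) on x, with
# intercept. Returns beta, se, chi2, p per row. Constant rows get
# beta = 0, p = 1.
ols_time <- function(Y, x) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx <= 0) abort("dates are constant")
  beta <- as.vector(Y %*% xc) / sxx
  ym <- rowMeans(Y)
  yss <- rowSums((Y - ym)^2)
  rss <- pmax(yss - beta^2 * sxx, 0)
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 / sxx)
  chi2 <- ifelse(se > 0, (beta / se)^2, ifelse(beta == 0, 0, Inf))
  const <- yss <= .Machine$double.eps * n * pmax(ym^2, 1)
  beta[const] <- 0
  se[const] <- NA_real_
  chi2[const] <- 0
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  list(beta = unname(beta), se = unname(se), chi2 = unname(chi2),
       p = unname(p))
}

#' Genomic control for chi-square test statistics
#'
#' The inflation factor is `lambda = median(chi2) / 0.45494` (the median of
#' a 1-df chi-square); all statistics are divided by `lambda` so the median
#' corrected p-value matches the null median. `lambda` is clamped at 1 (no
#' deflation).
#'
#' @param chi2_raw Numeric vector of 1-df chi-square statistics.
#' @return List with `lambda` (clamped), `lambda_raw`, `n_tests`,
#'   `chi2_gc`, `p_gc`.
#' @export
genomic_control <- function(chi2_raw) {
  chi2_raw <- chi2_raw[is.finite(chi2_raw) | chi2_raw == Inf]
  if (length(chi2_raw) < 2) abort("need at least 2 test statistics")
  lambda_raw <- median(chi2_raw) / qchisq(0.5, df = 1)
  lambda <- max(1, lambda_raw)
  chi2_gc <- chi2_raw / lambda
  p_gc <- pmax(pchisq(chi2_gc, df = 1, lower.tail = FALSE),
               .Machine$double.xmin)
  list(lambda = lambda, lambda_raw = lambda_raw,
       n_tests = length(chi2_raw), chi2_gc = chi2_gc, p_gc = p_gc)
}

#' Benjamini-Hochberg FDR call
#'
#' Step-up FDR control via [stats::p.adjust()]; also reports the largest
#' p-value declared significant (the implied p threshold of the scan).
#'
#' @param p_gc Numeric p-values.
#' @param q FDR level, in (0, 1).
#' @return List with `q_values`, `significant` (logical), and
#'   `implied_threshold` (`NA` if nothing is significant).
#' @export
fdr_call <- function(p_gc, q = 0.05) {
  if (q <= 0 || q >= 1) abort("q must lie in (0, 1)")
  if (any(p_gc < 0 | p_gc > 1, na.rm = TRUE)) abort("invalid p-values")
  q_values <- p.adjust(p_gc, method = "BH")
  significant <- !is.na(q_values) & q_values <= q
  implied <- if (any(significant)) max(p_gc[significant]) else NA_real_
  list(q_values = q_values, significant = significant,
       implied_threshold = implied)
}

#' Run the transcriptome-wide selection scan
#'
#' Per-gene OLS of predicted expression on forward time, genomic control on
#' the Wald chi-squares, and BH FDR calling.
#'
#' @param expr A [predict_expression()] result or a genes x samples matrix
#'   with sample ids as column names.
#' @param samples A [sample_table()] covering every expression column.
#' @param q FDR level.
#' @return A tibble of class `twss_result` with columns `gene_id`, `beta`,
#'   `se`, `chi2_raw`, `p_raw`, `chi2_gc`, `p_gc`, `q_value`,
#'   `significant`; attributes `lambda`, `lambda_raw`, `n_tests`,
#'   `implied_threshold`, `q`.
#' @export
run_twss <- function(expr, samples, q = 0.05) {
  Y <- if (inherits(expr, "predicted_expression")) expr$expression else expr
  if (is.null(colnames(Y))) abort("expression matrix needs sample column names")
  missing_s <- setdiff(colnames(Y), samples$sample_id)
  if (length(missing_s) > 0) abort("samples without dates in sample table")
  dates <- samples$date_bp[match(colnames(Y), samples$sample_id)]
  fit <- ols_time(Y, -dates)
  gc <- genomic_control(fit$chi2)
  fdr <- fdr_call(gc$p_gc, q = q)
  out <- tibble::tibble(
    gene_id = rownames(Y),
    beta = fit$beta, se = fit$se,
    chi2_raw = fit$chi2, p_raw = fit$p,
    chi2_gc = gc$chi2_gc, p_gc = gc$p_gc,
    q_value = fdr$q_values, significant = fdr$significant
  )
  attr(out, "lambda") <- gc$lambda
  attr(out, "lambda_raw") <- gc$lambda_raw
  attr(out, "n_tests") <- gc$n_tests
  attr(out, "implied_threshold") <- fdr$implied_threshold
  attr(out, "q") <- q
  class(out) <- c("twss_result", class(out))
  out
}

#' Date-randomization null for the transcriptome-wide scan
#'
#' Sample dates are permuted across individuals -- one permutation per
#' replicate, shared across genes so inter-gene correlation is preserved --
#' and the regression + genomic control pipeline is re-run. The pooled null
#' p-values form the gray reference cloud of a QQ plot.
#'
#' @inheritParams run_twss
#' @param n_perm Number of date permutations (>= 1).
#' @param seed Integer seed.
#' @return List with `p_gc` (pooled null p-values), `lambda` (per
#'   permutation), `n_perm`, and `qq` (tibble `expected`, `observed` of
#'   sorted null p-values).
#' @export
randomized_date_null <- function(expr, samples, n_perm, seed = 1L) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  Y <- if (inherits(expr, "predicted_expression")) expr$expression else expr
  dates <- samples$date_bp[match(colnames(Y), samples$sample_id)]
  set.seed(seed)
  p_all <- vector("list", n_perm)
  lambdas <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    fit <- ols_time(Y, -sample(dates))
    gc <- genomic_control(fit$chi2)
    p_all[[b]] <- gc$p_gc
    lambdas[b] <- gc$lambda_raw
  }
  p_gc <- unlist(p_all, use.names = FALSE)
  obs <- sort(p_gc)
  qq <- tibble::tibble(
    expected = (seq_along(obs) - 0.5) / length(obs),
    observed = obs
  )
  list(p_gc = p_gc, lambda = lambdas, n_perm = n_perm, qq = qq)
}

#' @exportS3Method generics::tidy
tidy.twss_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "twss_result")
  out
}

#' @exportS3Method generics::glance
glance.twss_result <- function(x, ...) {
  tibble::tibble(
    lambda = attr(x, "lambda"),
    lambda_raw = attr(x, "lambda_raw"),
    n_tests = attr(x, "n_tests"),
    n_significant = sum(x$significant),
    implied_threshold = attr(x, "implied_threshold"),
    q = attr(x, "q")
  )
}

#' @export
print.twss_result <- function(x, ...) {
  n_sig <- if ("significant" %in% names(x)) sum(x$significant) else NA
  cat(sprintf(
    "<twss_result> %d genes, lambda = %.3f, %s significant (q <= %g)\n",
    attr(x, "n_tests"), attr(x, "lambda"), format(n_sig), attr(x, "q")))
  NextMethod()
}

#' QQ plot of scan p-values
#'
#' Observed versus expected `-log10(p)` on the uniform null, optionally
#' overlaying a date-randomized null as gray reference points.
#'
#' @param object A `twss_result`.
#' @param null Optional [randomized_date_null()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.twss_result <- function(object, null = NULL, ...) {
  obs <- sort(object$p_gc)
  dat <- tibble::tibble(
    expected = -log10((seq_along(obs) - 0.5) / length(obs)),
    observed = -log10(obs)
  )
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$expected, .data$observed))
  if (!is.null(null)) {
    nd <- null$qq
    nd$expected <- -log10(nd$expected)
    nd$observed <- -log10(nd$observed)
    p <- p + ggplot2::geom_point(data = nd, color = "grey70", size = 0.6)
  }
  p +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(color = "steelblue", size = 0.8) +
    ggplot2::labs(x = "expected -log10(p)", y = "observed -log10(p)",
                  title = "Transcriptome-wide selection scan QQ")
}

#' Write scan results and run metadata
#'
#' @param result A `twss_result`.
#' @param path Output TSV path.
#' @param metadata_path Optional JSON path for run metadata (lambda, test
#'   counts, thresholds).
#' @param seed Optional seed to record in the metadata.
#' @export
write_twss <- function(result, path, metadata_path = NULL, seed = NULL) {
  readr::write_tsv(tidy(result), path, progress = FALSE)
  if (!is.null(metadata_path)) {
    meta <- as.list(glance(result))
    meta$seed <- seed
    jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}
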