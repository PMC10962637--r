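#' Site filters for the genome-wide selection scan
#'
#' Flags SNPs for retention: minor allele frequency (over all samples) at
#' least 0.1 (strict `< 0.1` dropped), missingness at most 90%, and minor
#' allele frequency nonzero among ancient samples.
#'
#' @param dataset A [genotype_dataset()].
#' @param samples A [sample_table()]; cohort `"ancient"` defines the
#'   ancient subset.
#' @return Tibble `snp_id`, `chrom`, `pos`, `maf`, `missingness`,
#'   `maf_ancient`, `retained`.
#' @export
filter_sites <- function(dataset, samples) {
  anc <- samples$sample_id[samples$cohort == "ancient"]
  anc <- intersect(anc, sample_ids(dataset))
  if (length(anc) == 0) abort("no dated ancient samples in dataset")
  f_all <- alt_frequency(dataset)
  f_anc <- alt_frequency(dataset, anc)
  maf <- pmin(f_all, 1 - f_all)
  maf_anc <- pmin(f_anc, 1 - f_anc)
  maf[is.nan(maf)] <- 0          # SNP missing in every sample
  maf_anc[is.nan(maf_anc)] <- 0  # SNP missing in every ancient sample
  miss <- colMeans(is.na(dataset$dosages))
  tibble::tibble(
    snp_id = dataset$snps$snp_id,
    chrom = dataset$snps$chrom,
    pos = dataset$snps$pos,
    maf = unname(maf),
    missingness = unname(miss),
    maf_ancient = unname(maf_anc),
    retained = unname(maf >= 0.1 & miss <= 0.9 & maf_anc > 0)
  )
}

#' Per-time-bin allele counts
#'
#' Samples are grouped into bins of `bin_years` by date; per SNP and bin the
#' alt-allele count and total allele count are accumulated. Dosages are
#' rounded to hard genotype calls for counting by default (expected dose
#' used when `dosage_counts = TRUE`), since the counts feed a binomial
#' likelihood.
#'
#' @param dataset A [genotype_dataset()].
#' @param samples A [sample_table()].
#' @param bin_years Bin width in years (default 100).
#' @param gen_time Years per generation, for the forward-time generation
#'   axis `gen = -date / gen_time`.
#' @param dosage_counts Use expected dosages instead of hard calls?
#' @return Tibble `snp_id`, `date_bp` (bin midpoint), `gen`, `d` (alt
#'   count), `n` (total alleles).
#' @export
bin_allele_counts <- function(dataset, samples, bin_years = 100,
                              gen_time = 28, dosage_counts = FALSE) {
  ids <- sample_ids(dataset)
  dates <- samples$date_bp[match(ids, samples$sample_id)]
  if (anyNA(dates)) abort("every genotype sample needs a date")
  bin <- floor(dates / bin_years)
  D <- dataset$dosages
  if (!dosage_counts) D <- round(D)
  out <- purrr::map_dfr(sort(unique(bin)), function(b) {
    rows <- which(bin == b)
    sub <- D[rows, , drop = FALSE]
    d <- colSums(sub, na.rm = TRUE)
    n <- 2 * colSums(!is.na(sub))
    mid <- (b + 0.5) * bin_years
    tibble::tibble(snp_id = dataset$snps$snp_id, date_bp = mid,
                   gen = -mid / gen_time, d = unname(d), n = unname(n))
  })
  out[out$n > 0, ]
}

#' Estimate a per-SNP selection coefficient from binned allele counts
#'
#' Scalar mode (default) maximizes the binomial log-likelihood of the
#' counts under a logistic frequency trajectory
#' `logit p(g) = a + s * g` over intercept and slope -- i.e. a binomial
#' GLM of the counts on the generation axis; the slope is the selection
#' coefficient per generation. Blocks mode makes `s` piecewise-constant on
#' `n_blocks` equal generation spans and adds a smoothness penalty
#' `smoothing * sum((s_{b+1} - s_b)^2)` to the negative log-likelihood;
#' as `smoothing -> Inf` it collapses to the scalar estimate.
#'
#' @param counts Tibble with columns `d`, `n` and either `gen` (forward
#'   generations) or `date_bp` (converted with `gen_time`). A `snp_id`
#'   column triggers per-SNP estimation over the whole table.
#' @param gen_time Years per generation (used only to convert `date_bp`).
#' @param mode `"scalar"` or `"blocks"`.
#' @param smoothing Penalty weight for blocks mode (default `10^4.5`).
#' @param n_blocks Number of blocks in blocks mode.
#' @return Tibble with one row per SNP: `snp_id` (if supplied), `s_hat`
#'   (scalar estimate, or block mean in blocks mode), `rms_s`, `converged`;
#'   blocks mode adds a list-column `s_path`. SNPs monomorphic across all
#'   bins get `NA` estimates with `converged = FALSE`.
#' @export
estimate_selection <- function(counts, gen_time = 28,
                               mode = c("scalar", "blocks"),
                               smoothing = 10^4.5, n_blocks = 5) {
  mode <- match.arg(mode)
  counts <- tibble::as_tibble(counts)
  if (!"gen" %in% names(counts)) {
    if (!"date_bp" %in% names(counts)) abort("counts need gen or date_bp")
    counts$gen <- -counts$date_bp / gen_time
  }
  if ("snp_id" %in% names(counts)) {
    parts <- split(counts, factor(counts$snp_id, levels = unique(counts$snp_id)))
    out <- purrr::map_dfr(parts, function(cc) {
      est <- estimate_selection_one(cc, mode, smoothing, n_blocks)
      est$snp_id <- cc$snp_id[1]
      est
    })
    return(out[, c("snp_id", setdiff(names(out), "snp_id"))])
  }
  estimate_selection_one(counts, mode, smoothing, n_blocks)
}

estimate_selection_one <- function(counts, mode, smoothing, n_blocks) {
  cc <- counts[counts$n > 0, ]
  if (nrow(cc) < 2) abort("need at least 2 bins with nonzero totals")
  if (all(cc$d == 0) || all(cc$d == cc$n)) {
    out <- tibble::tibble(s_hat = NA_real_, rms_s = NA_real_,
                          converged = FALSE)
    if (mode == "blocks") out$s_path <- list(NULL)
    return(out)
  }
  if (mode == "scalar") {
    fit <- suppressWarnings(
      glm(cbind(cc$d, cc$n - cc$d) ~ cc$gen, family = binomial())
    )
    s_hat <- unname(coef(fit)[2])
    return(tibble::tibble(s_hat = s_hat, rms_s = abs(s_hat),
                          converged = fit$converged))
  }
  # blocks mode: s piecewise-constant; logit p(g) = a + integral of s
  g <- cc$gen
  g0 <- min(g)
  breaks <- seq(g0, max(g), length.out = n_blocks + 1)
  span <- function(gi) {
    # per-block generation span covered up to gi
    pmax(pmin(gi, breaks[-1]) - breaks[-length(breaks)], 0)
  }
  X <- t(vapply(g, span, numeric(n_blocks)))
  nll <- function(par) {
    a <- par[1]; s <- par[-1]
    eta <- a + as.vector(X %*% s)
    p <- stats::plogis(eta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(cc$d * log(p) + (cc$n - cc$d) * log(1 - p)) +
      smoothing * sum(diff(s)^2)
  }
  start <- c(stats::qlogis(pmin(pmax(sum(cc$d) / sum(cc$n), 1e-6), 1 - 1e-6)),
             rep(0, n_blocks))
  opt <- optim(start, nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  s_path <- opt$par[-1]
  tibble::tibble(
    s_hat = mean(s_path),
    rms_s = sqrt(mean(s_path^2)),
    converged = opt$convergence == 0,
    s_path = list(s_path)
  )
}

#' Sliding 20-SNP windows of RMS selection coefficients
#'
#' Per chromosome, windows of `window` consecutive retained SNPs advance by
#' `step` SNPs; the window statistic is the mean of member `rms_s`. When the
#' sliding grid leaves trailing SNPs uncovered, one final partial window is
#' emitted (flagged) if it holds at least `step` SNPs. Chromosomes with
#' fewer than `step` estimable SNPs are skipped with a warning.
#'
#' @param estimates Tibble with `snp_id`, `chrom`, `pos`, `rms_s` (rows with
#'   `NA` `rms_s` are excluded), sorted or sortable by position.
#' @param window Window size in SNPs.
#' @param step Step in SNPs.
#' @return Tibble `chrom`, `start_pos`, `end_pos`, `n_snps`, `stat`,
#'   `partial`.
#' @export
window_scan <- function(estimates, window = 20, step = 10) {
  est <- estimates[!is.na(estimates$rms_s), ]
  est <- est[order(chrom_rank(est$chrom), est$pos), ]
  purrr::map_dfr(split(est, factor(est$chrom, levels = unique(est$chrom))),
                 function(ch) {
    n <- nrow(ch)
    if (n < step) {
      warn(paste0("chromosome ", ch$chrom[1], ": fewer than ", step,
                  " estimable SNPs, skipped"))
      return(NULL)
    }
    starts <- integer(0)
    partial <- logical(0)
    if (n >= window) {
      starts <- seq(1, n - window + 1, by = step)
      partial <- rep(FALSE, length(starts))
      last_end <- tail(starts, 1) + window - 1
      nxt <- tail(starts, 1) + step
      # a trailing partial window exists only when the full-window grid
      # leaves SNPs uncovered, and only if it holds >= step SNPs
      if (last_end < n && n - nxt + 1 >= step) {
        starts <- c(starts, nxt)
        partial <- c(partial, TRUE)
      }
    } else {
      starts <- 1L
      partial <- TRUE
    }
    purrr::map_dfr(seq_along(starts), function(i) {
      idx <- starts[i]:min(starts[i] + window - 1, n)
      tibble::tibble(
        chrom = ch$chrom[1],
        start_pos = ch$pos[idx[1]],
        end_pos = ch$pos[idx[length(idx)]],
        n_snps = length(idx),
        stat = mean(ch$rms_s[idx]),
        partial = partial[i]
      )
    })
  })
}

#' Gamma-fit p-values for window statistics
#'
#' A gamma distribution is fitted by maximum likelihood to all window
#' statistics (zeros replaced by half the smallest positive statistic,
#' logged); each window's p-value is the fitted upper-tail probability at
#' its statistic. If the ML fit fails, method-of-moments parameters are
#' used instead (logged).
#'
#' @param windows A [window_scan()] tibble (>= 50 windows).
#' @return `windows` with an added `p_window` column; attributes `shape`,
#'   `scale`, `fit_method`.
#' @export
gamma_pvalues <- function(windows) {
  if (nrow(windows) < 50) abort("need at least 50 windows for the gamma fit")
  x <- windows$stat
  if (any(x < 0)) abort("window statistics must be >= 0")
  if (any(x == 0)) {
    repl <- min(x[x > 0]) / 2
    message(sum(x == 0), " zero window statistic(s) replaced by ", repl)
    x[x == 0] <- repl
  }
  fit <- tryCatch({
    f <- fitdistrplus::fitdist(x, "gamma", method = "mle", keepdata = FALSE)
    list(shape = unname(f$estimate["shape"]),
         rate = unname(f$estimate["rate"]), method = "mle")
  }, error = function(e) {
    message("gamma ML fit failed (", conditionMessage(e),
            "); falling back to method of moments")
    m <- mean(x); v <- var(x)
    list(shape = m^2 / v, rate = m / v, method = "moments")
  })
  out <- windows
  out$p_window <- pmax(
    pgamma(x, shape = fit$shape, rate = fit$rate, lower.tail = FALSE),
    .Machine$double.xmin)
  attr(out, "shape") <- fit$shape
  attr(out, "scale") <- 1 / fit$rate
  attr(out, "fit_method") <- fit$method
  out
}

#' Merge significant windows into selection peaks
#'
#' Consecutive significant windows on the same chromosome closer than
#' `gap` bp are merged; each merged interval is then extended by `buffer`
#' bp on both sides. If gene coordinates are supplied, each peak reports
#' the number of overlapping genes overall, among modeled genes, and among
#' scan-significant genes (with the significant gene ids listed).
#'
#' @param windows A [gamma_pvalues()] result.
#' @param p_threshold Significance threshold on `p_window`; defaults to the
#'   BH-implied threshold at `q`.
#' @param q FDR level used for the default threshold.
#' @param gap Maximum inter-window distance (bp) for merging (default 5 Mb;
#'   strict `< gap` merges).
#' @param buffer Symmetric extension (bp) of each peak (default 0.1 Mb).
#' @param genes Optional tibble `gene_id`, `chrom`, `start`, `end`.
#' @param modeled_genes Optional character: gene ids with expression models.
#' @param significant_genes Optional character, or a `twss_result` from
#'   which significant gene ids are taken.
#' @return Tibble `chrom`, `start`, `end`, `n_windows`, `min_p`, and --
#'   when `genes` is given -- `n_all_genes`, `n_modeled_genes`,
#'   `n_significant_genes`, `twss_significant`.
#' @export
merge_peaks <- function(windows, p_threshold = NULL, q = 0.05,
                        gap = 5e6, buffer = 1e5,
                        genes = NULL, modeled_genes = NULL,
                        significant_genes = NULL) {
  if (inherits(significant_genes, "twss_result")) {
    significant_genes <-
      significant_genes$gene_id[significant_genes$significant]
  }
  if (is.null(p_threshold)) {
    fdr <- fdr_call(windows$p_window, q = q)
    sig <- fdr$significant
  } else {
    sig <- windows$p_window <= p_threshold
  }
  sw <- windows[sig, ]
  if (nrow(sw) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_windows = integer(),
                          min_p = numeric()))
  }
  sw <- sw[order(chrom_rank(sw$chrom), sw$start_pos), ]
  peaks <- purrr::map_dfr(split(sw, factor(sw$chrom, levels = unique(sw$chrom))),
                          function(ch) {
    res <- list()
    cur <- ch[1, ]
    cur_start <- cur$start_pos; cur_end <- cur$end_pos
    cur_n <- 1L; cur_p <- cur$p_window
    if (nrow(ch) > 1) for (i in 2:nrow(ch)) {
      w <- ch[i, ]
      if (w$start_pos - cur_end < gap) {
        cur_end <- max(cur_end, w$end_pos)
        cur_n <- cur_n + 1L
        cur_p <- min(cur_p, w$p_window)
      } else {
        res[[length(res) + 1]] <- tibble::tibble(
          chrom = w$chrom, start = cur_start, end = cur_end,
          n_windows = cur_n, min_p = cur_p)
        cur_start <- w$start_pos; cur_end <- w$end_pos
        cur_n <- 1L; cur_p <- w$p_window
      }
    }
    res[[length(res) + 1]] <- tibble::tibble(
      chrom = ch$chrom[1], start = cur_start, end = cur_end,
      n_windows = cur_n, min_p = cur_p)
    dplyr::bind_rows(res)
  })
  peaks$start <- pmax(peaks$start - buffer, 1)
  peaks$end <- peaks$end + buffer

  if (!is.null(genes)) {
    genes <- tibble::as_tibble(genes)
    overlap <- function(pk) {
      hits <- genes$chrom == pk$chrom &
        genes$start <= pk$end & genes$end >= pk$start
      genes$gene_id[hits]
    }
    info <- purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
      hit <- overlap(peaks[i, ])
      tibble::tibble(
        n_all_genes = length(hit),
        n_modeled_genes = if (is.null(modeled_genes)) NA_integer_ else
          length(intersect(hit, modeled_genes)),
        n_significant_genes = if (is.null(significant_genes)) NA_integer_ else
          length(intersect(hit, significant_genes)),
        twss_significant = if (is.null(significant_genes)) NA_character_ else
          paste(intersect(hit, significant_genes), collapse = ",")
      )
    })
    peaks <- dplyr::bind_cols(peaks, info)
  }
  peaks
}

#' Run the genome-wide selection scan
#'
#' Chains [filter_sites()], [bin_allele_counts()], [estimate_selection()],
#' [window_scan()], [gamma_pvalues()] and [merge_peaks()]. Externally
#' computed per-SNP estimates (e.g. from a dedicated time-series selection
#' model) can be plugged in through `estimates`, skipping the internal
#' estimator.
#'
#' @inheritParams bin_allele_counts
#' @inheritParams merge_peaks
#' @param window,step Window layout in SNPs.
#' @param estimates Optional tibble `snp_id`, `s_hat` (and/or `rms_s`)
#'   replacing the internal estimator.
#' @param mode,smoothing Passed to [estimate_selection()].
#' @return List of class `gwss_result`: `sites`, `estimates`, `windows`
#'   (with gamma p-values), `peaks`.
#' @export
run_gwss <- function(dataset, samples, bin_years = 100, gen_time = 28,
                     window = 20, step = 10, q = 0.05,
                     gap = 5e6, buffer = 1e5,
                     mode = "scalar", smoothing = 10^4.5,
                     estimates = NULL, genes = NULL,
                     modeled_genes = NULL, significant_genes = NULL,
                     dosage_counts = FALSE) {
  sites <- filter_sites(dataset, samples)
  retained <- sites$snp_id[sites$retained]
  if (is.null(estimates)) {
    counts <- bin_allele_counts(dataset, samples, bin_years = bin_years,
                                gen_time = gen_time,
                                dosage_counts = dosage_counts)
    counts <- counts[counts$snp_id %in% retained, ]
    estimates <- estimate_selection(counts, gen_time = gen_time,
                                    mode = mode, smoothing = smoothing)
  } else {
    estimates <- tibble::as_tibble(estimates)
    if (!"rms_s" %in% names(estimates)) estimates$rms_s <- abs(estimates$s_hat)
    estimates <- estimates[estimates$snp_id %in% retained, ]
  }
  est <- dplyr::inner_join(
    estimates, sites[, c("snp_id", "chrom", "pos")], by = "snp_id")
  windows <- window_scan(est, window = window, step = step)
  windows <- gamma_pvalues(windows)
  peaks <- merge_peaks(windows, q = q, gap = gap, buffer = buffer,
                       genes = genes, modeled_genes = modeled_genes,
                       significant_genes = significant_genes)
  structure(list(sites = sites, estimates = est, windows = windows,
                 peaks = peaks),
            class = "gwss_result")
}

#' @export
print.gwss_result <- function(x, ...) {
  cat(sprintf(
    "<gwss_result> %d/%d SNPs retained, %d windows, %d peak(s)\n",
    sum(x$sites$retained), nrow(x$sites), nrow(x$windows), nrow(x$peaks)))
  invisible(x)
}

#' Window p-value plot for the genome-wide scan
#'
#' `-log10(p)` of each 20-SNP window along the genome.
#'
#' @param object A `gwss_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gwss_result <- function(object, ...) {
  w <- object$windows
  w$mid <- (w$start_pos + w$end_pos) / 2
  ggplot2::ggplot(w, ggplot2::aes(.data$mid, -log10(.data$p_window))) +
    ggplot2::geom_point(size = 0.7, color = "grey30") +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "-log10(window p)",
                  title = "Genome-wide selection scan")
}

#' Write window and peak tables
#'
#' `write_windows` emits the window TSV; `write_peaks_bed` a BED file
#' (0-based half-open); `write_peaks` a peak summary TSV with gene counts.
#'
#' @param windows,peaks Tibbles from [gamma_pvalues()] / [merge_peaks()].
#' @param path Output path.
#' @export
write_windows <- function(windows, path) {
  readr::write_tsv(tibble::as_tibble(windows), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_windows
#' @export
write_peaks_bed <- function(peaks, path) {
  bed <- tibble::tibble(chrom = peaks$chrom,
                        start = format(peaks$start - 1, scientific = FALSE, trim = TRUE),
                        end = format(peaks$end, scientific = FALSE, trim = TRUE))
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_windows
#' @export
write_peaks <- function(peaks, path) {
  readr::write_tsv(tibble::as_tibble(peaks), path, progress = FALSE)
  invisible(path)
}
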