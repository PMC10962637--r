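make_filter_fixture <- function() {
  # 5 ancient + 5 modern samples, 4 SNPs with known filter outcomes
  dos <- cbind(
    s1 = c(0, 0, 0, 0, 0, 2, 2, 2, 1, 1),   # fixed in ancients -> dropped
    s2 = c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0),   # MAF exactly 0.10 -> retained
    s3 = c(1, NA, NA, NA, NA, NA, NA, NA, NA, NA),  # 90% missing -> retained
    s4 = c(0, 0, 1, 0, 0, 0, 0, 0, 0, 0)    # MAF 0.05 -> dropped
  )
  ds <- tiny_dataset(dos)
  smp <- sample_table(rownames(ds$dosages), c(rep(3000, 5), rep(0, 5)))
  list(ds = ds, smp = smp)
}

test_that("site filters apply the MAF, missingness and ancient-MAF rules", {
  fx <- make_filter_fixture()
  st <- filter_sites(fx$ds, fx$smp)
  expect_equal(st$retained, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(st$maf[2], 0.1)
  expect_equal(st$missingness[3], 0.9)
})

test_that("site filter bookkeeping matches a hand computation on a random panel", {
  set.seed(80)
  n_s <- 40; n_i <- 30
  dos <- matrix(sample(0:2, n_s * n_i, replace = TRUE,
                       prob = c(0.7, 0.2, 0.1)), nrow = n_i)
  dos[sample(length(dos), 150)] <- NA
  ds <- tiny_dataset(dos)
  smp <- sample_table(rownames(ds$dosages), c(rep(2500, 20), rep(0, 10)))
  st <- filter_sites(ds, smp)
  # independent recomputation, one SNP at a time
  for (j in seq_len(n_s)) {
    x <- dos[, j]
    f <- mean(x, na.rm = TRUE) / 2
    maf <- min(f, 1 - f)
    fa <- mean(x[1:20], na.rm = TRUE) / 2
    mafa <- min(fa, 1 - fa)
    if (is.nan(mafa)) mafa <- 0
    keep <- maf >= 0.1 && mean(is.na(x)) <= 0.9 && mafa > 0
    expect_equal(st$retained[st$snp_id == ds$snps$snp_id[j]], keep)
  }
})

test_that("scalar estimator recovers the slope of an exact logistic trajectory", {
  gens <- seq(-160, 0, by = 10)
  p <- stats::plogis(0.5 + 0.01 * gens)
  counts <- tibble::tibble(gen = gens, n = 1e6, d = round(1e6 * p))
  est <- estimate_selection(counts)
  expect_lt(abs(est$s_hat - 0.01), 0.001)
  expect_true(est$converged)
  expect_equal(est$rms_s, abs(est$s_hat))
})

test_that("a time-constant frequency gives s_hat near zero", {
  counts <- tibble::tibble(gen = seq(-150, 0, by = 15), n = 1e6, d = 4e5)
  est <- estimate_selection(counts)
  expect_lt(abs(est$s_hat), 1e-8)
})

test_that("s_hat is antisymmetric under allele relabeling", {
  set.seed(81)
  gens <- seq(-120, 0, by = 12)
  p <- stats::plogis(-0.3 + 0.015 * gens)
  counts <- tibble::tibble(gen = gens, n = 500,
                           d = rbinom(length(gens), 500, p))
  a <- estimate_selection(counts)
  swapped <- dplyr::mutate(counts, d = n - d)
  b <- estimate_selection(swapped)
  expect_equal(b$s_hat, -a$s_hat, tolerance = 1e-6)
})

test_that("blocks mode collapses to the scalar estimate as smoothing grows", {
  gens <- seq(-160, 0, by = 8)
  p <- stats::plogis(0.2 + 0.012 * gens)
  counts <- tibble::tibble(gen = gens, n = 1e5, d = round(1e5 * p))
  sc <- estimate_selection(counts, mode = "scalar")
  bl <- estimate_selection(counts, mode = "blocks", smoothing = 1e10,
                           n_blocks = 4)
  expect_equal(bl$s_hat, sc$s_hat, tolerance = 1e-3)
  expect_equal(bl$rms_s, abs(sc$s_hat), tolerance = 1e-3)
  expect_equal(length(bl$s_path[[1]]), 4)
})

test_that("monomorphic SNPs are flagged, not estimated", {
  counts <- tibble::tibble(snp_id = rep(c("a", "b"), each = 3),
                           gen = rep(c(-100, -50, 0), 2),
                           n = 100, d = c(0, 0, 0, 10, 40, 70))
  est <- estimate_selection(counts)
  expect_true(is.na(est$s_hat[est$snp_id == "a"]))
  expect_false(est$converged[est$snp_id == "a"])
  expect_true(est$converged[est$snp_id == "b"])
  expect_error(estimate_selection(tibble::tibble(gen = 0, n = 10, d = 5)),
               "at least 2 bins")
})

test_that("40 SNPs yield exactly three full 20-SNP windows", {
  est <- tibble::tibble(snp_id = paste0("s", 1:40), chrom = "1",
                        pos = (1:40) * 1e4, rms_s = 0.01)
  w <- window_scan(est)
  expect_equal(nrow(w), 3)
  expect_equal(w$start_pos, c(1, 11, 21) * 1e4)
  expect_equal(w$end_pos, c(20, 30, 40) * 1e4)
  expect_false(any(w$partial))
  expect_equal(w$stat, rep(0.01, 3))
})

test_that("trailing SNPs form one flagged partial window when >= 10 remain", {
  est <- tibble::tibble(snp_id = paste0("s", 1:45), chrom = "1",
                        pos = (1:45) * 1e4, rms_s = 0.01)
  w <- window_scan(est)
  expect_equal(nrow(w), 4)
  expect_equal(w$partial, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(w$n_snps[4], 15)

  est15 <- est[1:15, ]
  w15 <- window_scan(est15)
  expect_equal(nrow(w15), 1)
  expect_true(w15$partial)

  expect_warning(window_scan(est[1:9, ]), "skipped")
})

test_that("window statistics equal a brute-force recomputation", {
  set.seed(82)
  est <- tibble::tibble(snp_id = paste0("s", 1:57),
                        chrom = rep(c("1", "2"), c(33, 24)),
                        pos = c((1:33) * 1e4, (1:24) * 1e4),
                        rms_s = abs(rnorm(57, 0, 0.01)))
  w <- window_scan(est)
  for (i in seq_len(nrow(w))) {
    members <- est$rms_s[est$chrom == w$chrom[i] &
                           est$pos >= w$start_pos[i] &
                           est$pos <= w$end_pos[i]]
    expect_equal(w$stat[i], mean(members), tolerance = 1e-12)
    expect_equal(w$n_snps[i], length(members))
  }
})

test_that("gamma fit recovers parameters and p-values behave", {
  set.seed(83)
  w <- tibble::tibble(chrom = "1", start_pos = 1:1e4, end_pos = 1:1e4,
                      n_snps = 20, stat = rgamma(1e4, shape = 2, scale = 0.01),
                      partial = FALSE)
  fitted <- gamma_pvalues(w)
  expect_lt(abs(attr(fitted, "shape") - 2), 0.05)
  expect_gt(stats::ks.test(fitted$p_window, "punif")$p.value, 0.01)
  expect_equal(which.min(fitted$p_window), which.max(w$stat))

  dup <- gamma_pvalues(dplyr::bind_rows(w, w))
  expect_equal(attr(dup, "shape"), attr(fitted, "shape"), tolerance = 1e-3)

  expect_error(gamma_pvalues(w[1:10, ]), "at least 50")
  wz <- w[1:60, ]
  wz$stat[1] <- 0
  expect_message(gamma_pvalues(wz), "zero window")
})

test_that("peak merging follows the 5 Mb gap and 0.1 Mb buffer rules", {
  mk <- function(s1, e1, s2, e2) tibble::tibble(
    chrom = "1", start_pos = c(s1, s2), end_pos = c(e1, e2),
    n_snps = 20, stat = 0.02, partial = FALSE, p_window = 1e-6)
  near <- merge_peaks(mk(1e6, 1.1e6, 6.0e6, 6.1e6), p_threshold = 1e-4)
  expect_equal(nrow(near), 1)           # 4.9 Mb apart -> merged
  far <- merge_peaks(mk(1e6, 1.1e6, 6.2e6, 6.3e6), p_threshold = 1e-4)
  expect_equal(nrow(far), 2)            # 5.1 Mb apart -> separate

  single <- merge_peaks(tibble::tibble(
    chrom = "1", start_pos = 1e6, end_pos = 1.05e6, n_snps = 20,
    stat = 0.02, partial = FALSE, p_window = 1e-6), p_threshold = 1e-4)
  expect_equal(single$start, 9e5)
  expect_equal(single$end, 1.15e6)
})

test_that("peak merging and gene counts match brute-force oracles", {
  set.seed(84)
  for (rep in 1:20) {
    n_w <- sample(5:40, 1)
    w <- tibble::tibble(
      chrom = sample(c("1", "2"), n_w, replace = TRUE),
      start_pos = sample.int(5e7, n_w), n_snps = 20, stat = 0.02,
      partial = FALSE, p_window = runif(n_w)^3)
    w$end_pos <- w$start_pos + sample.int(2e5, n_w)
    w <- w[order(w$chrom, w$start_pos), ]
    thr <- 0.05
    if (!any(w$p_window <= thr)) next
    genes <- tibble::tibble(
      gene_id = paste0("g", 1:30),
      chrom = sample(c("1", "2"), 30, replace = TRUE),
      start = sample.int(5e7, 30))
    genes$end <- genes$start + sample.int(1e5, 30)
    got <- merge_peaks(w, p_threshold = thr, genes = genes)
    want <- merge_oracle(w, thr, gap = 5e6, buffer = 1e5)
    expect_equal(nrow(got), nrow(want))
    got_o <- got[order(got$chrom, got$start), ]
    want_o <- want[order(want$chrom, want$start), ]
    expect_equal(got_o$start, want_o$start)
    expect_equal(got_o$end, want_o$end)
    for (i in seq_len(nrow(got_o))) {
      expect_equal(got_o$n_all_genes[i],
                   overlap_count_oracle(genes, got_o$chrom[i],
                                        got_o$start[i], got_o$end[i]))
    }
  }
})

test_that("external per-SNP estimates can be plugged into the scan", {
  set.seed(85)
  cfg <- sim_config(seed = 86, sample_schedule = tibble::tibble(
    date_bp = c(4000, 2000, 0), n = c(30, 30, 30)))
  traj <- twasscan:::simulate_trajectories(runif(700, 0.2, 0.8), 0,
                                           cfg$n_generations, 1e4)
  co <- simulate_cohort(cfg, traj)
  ext <- tibble::tibble(snp_id = co$dataset$snps$snp_id,
                        s_hat = rnorm(700, 0, 0.01))
  gw <- run_gwss(co$dataset, co$samples, estimates = ext)
  expect_s3_class(gw$windows, "tbl_df")
  expect_true(all(gw$estimates$rms_s == abs(ext$s_hat[
    match(gw$estimates$snp_id, ext$snp_id)])))
})
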