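# Shared fixture builders and independent oracles. Oracles here are written
# deliberately as naive loops / closed forms so they stay independent of the
# package's vectorized implementations.

# Small genotype dataset from an explicit samples x SNPs dosage matrix.
tiny_dataset <- function(dos, ref = "A", alt = "G", chrom = "1", r2 = NULL,
                         pos = NULL) {
  n_snp <- ncol(dos)
  snps <- tibble::tibble(
    snp_id = paste0("s", seq_len(n_snp)),
    chrom = rep_len(chrom, n_snp),
    pos = if (is.null(pos)) seq_len(n_snp) * 1000L else pos,
    ref = rep_len(ref, n_snp),
    alt = rep_len(alt, n_snp),
    imputation_r2 = if (is.null(r2)) rep(1, n_snp) else r2
  )
  rownames(dos) <- paste0("i", seq_len(nrow(dos)))
  colnames(dos) <- snps$snp_id
  genotype_dataset(snps, dos)
}

# Weight-model tibble for a single gene over the ids of a tiny_dataset.
tiny_model <- function(snp_ids, weights, effect = "G", other = "A",
                       gene = "g1", tissue = "T1", r2 = 0.5) {
  w <- tibble::tibble(
    gene_id = gene, tissue = tissue,
    snp_id = snp_ids,
    effect_allele = rep_len(effect, length(snp_ids)),
    other_allele = rep_len(other, length(snp_ids)),
    weight = weights, training_r2 = r2
  )
  class(w) <- c("gene_models", class(w))
  w
}

# Independent BH step-up: largest k with p_(k) <= k q / m.
bh_stepup_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  k <- which(p[o] <= q * seq_len(m) / m)
  rej <- logical(m)
  if (length(k) > 0) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# Naive per-sample prediction: explicit loop with orientation flips and
# missing-dose fill at 2 * alt frequency.
predict_oracle <- function(dataset, model_tbl) {
  D <- dataset$dosages
  snps <- dataset$snps
  freq <- colMeans(D, na.rm = TRUE) / 2
  out <- numeric(nrow(D))
  for (smp in seq_len(nrow(D))) {
    acc <- 0
    for (r in seq_len(nrow(model_tbl))) {
      j <- match(model_tbl$snp_id[r], snps$snp_id)
      if (is.na(j)) next
      ea <- model_tbl$effect_allele[r]
      if (ea != snps$alt[j] && ea != snps$ref[j]) next
      d <- D[smp, j]
      if (is.na(d)) d <- 2 * freq[j]
      if (ea == snps$ref[j]) d <- 2 - d
      acc <- acc + model_tbl$weight[r] * d
    }
    out[smp] <- acc
  }
  out
}

# Naive gene-level z: polarize, then weighted sum / sqrt(sum of squares).
gene_z_oracle <- function(weights, effect, other, score_allele, score,
                          denominator = "scored") {
  pol <- numeric(length(weights))
  scored <- logical(length(weights))
  for (i in seq_along(weights)) {
    if (is.na(score[i])) next
    if (is.na(score_allele[i]) || score_allele[i] == effect[i]) {
      pol[i] <- score[i]; scored[i] <- TRUE
    } else if (score_allele[i] == other[i]) {
      pol[i] <- -score[i]; scored[i] <- TRUE
    }
  }
  if (!any(scored)) return(NA_real_)
  den2 <- if (denominator == "scored") sum(weights[scored]^2) else
    sum(weights^2)
  if (den2 == 0) return(NA_real_)
  sum(weights[scored] * pol[scored]) / sqrt(den2)
}

# Naive interval merge (+ buffer) over significant windows of one result.
merge_oracle <- function(windows, p_threshold, gap, buffer) {
  sw <- windows[windows$p_window <= p_threshold, ]
  sw <- sw[order(sw$chrom, sw$start_pos), ]
  peaks <- list()
  for (ch in unique(sw$chrom)) {
    w <- sw[sw$chrom == ch, ]
    start <- w$start_pos[1]; end <- w$end_pos[1]
    if (nrow(w) > 1) for (i in 2:nrow(w)) {
      if (w$start_pos[i] - end < gap) {
        end <- max(end, w$end_pos[i])
      } else {
        peaks[[length(peaks) + 1]] <- c(ch, start, end)
        start <- w$start_pos[i]; end <- w$end_pos[i]
      }
    }
    peaks[[length(peaks) + 1]] <- c(ch, start, end)
  }
  out <- do.call(rbind, peaks)
  data.frame(chrom = out[, 1],
             start = pmax(as.numeric(out[, 2]) - buffer, 1),
             end = as.numeric(out[, 3]) + buffer)
}

# Count genes overlapping an interval by brute force.
overlap_count_oracle <- function(genes, chrom, start, end) {
  n <- 0
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] == chrom &&
        genes$start[i] <= end && genes$end[i] >= start) n <- n + 1
  }
  n
}

# Minimal hand-written VCF text with GT genotypes.
write_gt_vcf <- function(path, rows, samples) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, rows), path)
}
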