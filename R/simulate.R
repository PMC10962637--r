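#' Simulation configuration for synthetic dated cohorts
#'
#' Bundles the population-genetic and sampling parameters used by the
#' synthetic-data generator. Defaults reproduce the study design the scans
#' are built around: a closed population of effective size `Ne = 10^4`
#' sampled over a 4,500-year transect, 616 ancient individuals plus 91
#' present-day individuals.
#'
#' @param effective_population_size Diploid effective population size `Ne`.
#' @param generation_time Years per generation. The literature offers no
#'   single canonical value; 28 is used here and is configurable.
#' @param n_generations Number of Wright-Fisher generations simulated.
#'   Defaults to `ceiling(4500 / generation_time)` so the horizon covers the
#'   4,500-year transect.
#' @param sample_schedule Tibble with columns `date_bp` and `n`: how many
#'   individuals to draw at each date (years before present). The default
#'   draws 77 individuals at each of 4500, 4000, ..., 1000 BP (616 ancient)
#'   and 91 at present.
#' @param imputation_quality_range Length-2 numeric in `[0, 1]`; per-SNP
#'   imputation quality is drawn uniformly from this interval.
#' @param seed Integer seed governing all randomness downstream.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(effective_population_size = 1e4,
                       generation_time = 28,
                       n_generations = ceiling(4500 / generation_time),
                       sample_schedule = default_schedule(),
                       imputation_quality_range = c(0.5, 1),
                       seed = 1L) {
  if (effective_population_size < 2) abort("Ne must be >= 2")
  if (generation_time <= 0) abort("generation_time must be positive")
  if (n_generations < 1) abort("n_generations must be >= 1")
  sample_schedule <- tibble::as_tibble(sample_schedule)
  if (nrow(sample_schedule) == 0) abort("sample_schedule must not be empty")
  if (!all(c("date_bp", "n") %in% names(sample_schedule))) {
    abort("sample_schedule needs columns date_bp and n")
  }
  if (any(sample_schedule$date_bp < 0)) abort("sample dates must be >= 0")
  q <- imputation_quality_range
  if (length(q) != 2 || any(q < 0) || any(q > 1) || q[1] > q[2]) {
    abort("imputation_quality_range must be an interval within [0, 1]")
  }
  horizon_years <- n_generations * generation_time
  if (any(sample_schedule$date_bp > horizon_years)) {
    abort("sample_schedule dates must fall inside the simulated horizon")
  }
  structure(list(
    effective_population_size = effective_population_size,
    generation_time = generation_time,
    n_generations = as.integer(n_generations),
    sample_schedule = sample_schedule,
    imputation_quality_range = q,
    seed = as.integer(seed)
  ), class = "sim_config")
}

default_schedule <- function() {
  tibble::tibble(
    date_bp = c(seq(4500, 1000, by = -500), 0),
    n = c(rep(77L, 8), 91L)
  )
}

#' Simulate a Wright-Fisher allele-frequency trajectory
#'
#' One locus under genic (multiplicative) selection: each generation the
#' post-selection frequency is `p' = p(1+s) / (p(1+s) + (1-p))` and the next
#' generation's count is drawn as `Binomial(2*Ne, p')`. Frequencies 0 and 1
#' are absorbing.
#'
#' @param p0 Initial allele frequency in `[0, 1]`.
#' @param s Selection coefficient per generation; either a scalar
#'   (time-constant) or a vector of length `n_gen` (piecewise).
#' @param n_gen Number of generations to simulate.
#' @param Ne Diploid effective population size (>= 2).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n_gen + 1`: the frequency path,
#'   starting at `p0`.
#' @export
simulate_trajectory <- function(p0, s, n_gen, Ne, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(!is.finite(s))) abort("s must be finite")
  if (n_gen < 0) abort("n_gen must be >= 0")
  if (p0 < 0 || p0 > 1) abort("p0 must lie in [0, 1]")
  if (Ne < 2) abort("Ne must be >= 2")
  s_path <- if (length(s) == 1) rep(s, n_gen) else s
  if (n_gen > 0 && length(s_path) != n_gen) {
    abort("length(s) must be 1 or n_gen")
  }
  traj <- simulate_trajectories(p0, matrix(s_path, ncol = 1), n_gen, Ne)
  drop(traj)
}

# Vectorized Wright-Fisher over many loci. `s` is a scalar, a per-locus
# vector, or an n_gen x n_loci matrix for piecewise selection. Returns an
# (n_gen + 1) x n_loci matrix of frequencies.
simulate_trajectories <- function(p0, s, n_gen, Ne) {
  n_loci <- length(p0)
  if (is.matrix(s)) {
    n_loci <- max(n_loci, ncol(s))
  } else {
    n_loci <- max(n_loci, length(s))
  }
  p0 <- rep_len(p0, n_loci)
  out <- matrix(NA_real_, nrow = n_gen + 1, ncol = n_loci)
  out[1, ] <- p0
  p <- p0
  two_ne <- 2 * Ne
  for (g in seq_len(n_gen)) {
    sg <- if (is.matrix(s)) s[g, ] else rep_len(s, n_loci)
    psel <- p * (1 + sg) / (p * (1 + sg) + (1 - p))
    p <- rbinom(n_loci, two_ne, psel) / two_ne
    out[g + 1, ] <- p
  }
  out
}

# Map a date (years BP) to a row index of the trajectory matrix
# (1 = oldest generation, n_gen + 1 = present).
generation_row <- function(date_bp, config) {
  horizon <- config$n_generations * config$generation_time
  g <- round((horizon - date_bp) / config$generation_time)
  if (any(g < 0 | g > config$n_generations)) {
    abort("date outside the simulated horizon")
  }
  as.integer(g) + 1L
}

#' Simulate a dated genotype cohort from allele-frequency trajectories
#'
#' For each individual scheduled at date `d`, the genotype at each SNP is
#' drawn `Binomial(2, p_d)` from the frequency at that generation. An
#' imputation-noise step then shrinks the dosage toward the population mean
#' `2 p_d` with weight `1 - q`, where `q` is the SNP's imputation quality
#' (drawn uniformly from `config$imputation_quality_range` and recorded as
#' the SNP's `imputation_r2`): `dose = q * geno + (1 - q) * 2 p_d`. With
#' `q = 1` dosages are exact genotypes; with `q = 0` every dosage collapses
#' to `2 p_d` and carries no individual signal.
#'
#' @param config A [sim_config()].
#' @param trajectories `(n_gen + 1) x n_snps` matrix of frequencies with
#'   column names = SNP ids (as from [simulate_trajectories]).
#' @param snps Optional SNP tibble (`snp_id`, `chrom`, `pos`, `ref`, `alt`);
#'   generated (chromosome "1", 5 kb spacing, A/G alleles) when `NULL`.
#' @return List with `dataset` (a [genotype_dataset()]) and `samples`
#'   (a [sample_table()]).
#' @export
simulate_cohort <- function(config, trajectories, snps = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sched <- config$sample_schedule
  if (nrow(sched) == 0) abort("empty sample schedule")
  set.seed(config$seed + 1L)
  n_snp <- ncol(trajectories)
  ids <- colnames(trajectories)
  if (is.null(ids)) ids <- sprintf("snp%05d", seq_len(n_snp))
  if (is.null(snps)) {
    snps <- tibble::tibble(
      snp_id = ids, chrom = "1", pos = 5000L * seq_len(n_snp),
      ref = "A", alt = "G"
    )
  }
  qr <- config$imputation_quality_range
  q <- runif(n_snp, qr[1], qr[2])
  snps$imputation_r2 <- q

  rows <- generation_row(sched$date_bp, config)
  n_total <- sum(sched$n)
  dos <- matrix(NA_real_, nrow = n_total, ncol = n_snp)
  date_vec <- numeric(n_total)
  at <- 0L
  for (i in seq_len(nrow(sched))) {
    n_i <- sched$n[i]
    p <- trajectories[rows[i], ]
    geno <- matrix(rbinom(n_i * n_snp, 2L, rep(p, each = n_i)), nrow = n_i)
    mean_dose <- matrix(2 * p, nrow = n_i, ncol = n_snp, byrow = TRUE)
    qmat <- matrix(q, nrow = n_i, ncol = n_snp, byrow = TRUE)
    dos[at + seq_len(n_i), ] <- qmat * geno + (1 - qmat) * mean_dose
    date_vec[at + seq_len(n_i)] <- sched$date_bp[i]
    at <- at + n_i
  }
  sample_id <- sprintf("ind%04d", seq_len(n_total))
  rownames(dos) <- sample_id
  colnames(dos) <- ids
  list(
    dataset = genotype_dataset(snps, dos),
    samples = sample_table(sample_id, date_vec)
  )
}

#' Simulate sparse cis-eQTL weight models with known ground truth
#'
#' Each gene receives a sparse linear weight model over a contiguous block of
#' SNPs (emulating a cis window); model sizes are drawn with median ~12
#' SNPs. For genes designated as selected, every member SNP is assigned a
#' selection coefficient whose sign is matched to
#' `sign(weight) * direction`, so that allele-frequency shifts push predicted
#' expression in the intended direction.
#'
#' @param n_genes Number of genes to model.
#' @param snps_per_gene Either a single count (fixed model size), a vector of
#'   length `n_genes`, or a function `n -> sizes`. Default: lognormal sizes
#'   with median 12.
#' @param weight_scale SD of the Normal(0, weight_scale) weights, in
#'   expression-SD per effect-allele copy.
#' @param selected_genes Optional tibble with columns `gene` (index into the
#'   simulated genes), `direction` (+1 expression up, -1 down) and `s`
#'   (selection-coefficient magnitude per generation).
#' @param seed Optional integer seed.
#' @param snps Optional SNP tibble (`snp_id`, `ref`, `alt`); invented when
#'   `NULL`, sized exactly to tile the models.
#' @param flip_fraction Fraction of model SNPs whose effect allele is the
#'   ref rather than the alt allele (exercises allele orientation).
#'
#' @return List with `weights` (tibble: `gene_id`, `tissue`, `snp_id`,
#'   `effect_allele`, `other_allele`, `weight`), `summary` (tibble:
#'   `gene_id`, `tissue`, `training_r2`), and `architecture` (list:
#'   `selection_map` named per-SNP s on the alt-allele scale, `selected`
#'   tibble, `snps` tibble).
#' @export
simulate_gene_models <- function(n_genes,
                                 snps_per_gene = NULL,
                                 weight_scale = 0.15,
                                 selected_genes = NULL,
                                 seed = NULL,
                                 snps = NULL,
                                 flip_fraction = 0.2) {
  if (!is.null(seed)) set.seed(seed)
  if (n_genes < 1) abort("n_genes must be >= 1")
  sizes <- if (is.null(snps_per_gene)) {
    pmax(1L, as.integer(round(stats::rlnorm(n_genes, log(12), 0.4))))
  } else if (is.function(snps_per_gene)) {
    as.integer(snps_per_gene(n_genes))
  } else if (length(snps_per_gene) == 1) {
    rep(as.integer(snps_per_gene), n_genes)
  } else {
    as.integer(rep_len(snps_per_gene, n_genes))
  }
  n_snp_needed <- sum(sizes)
  if (is.null(snps)) {
    snps <- tibble::tibble(
      snp_id = sprintf("snp%05d", seq_len(n_snp_needed)),
      ref = "A", alt = "G"
    )
  } else {
    snps <- tibble::as_tibble(snps)
    if (nrow(snps) < n_snp_needed) {
      abort("not enough SNPs to tile the requested gene models")
    }
  }
  gene_id <- sprintf("gene%04d", seq_len(n_genes))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L

  flip <- runif(n_snp_needed) < flip_fraction
  weights <- tibble::tibble(
    gene_id = rep(gene_id, sizes),
    tissue = "SyntheticTissue",
    snp_id = snps$snp_id[seq_len(n_snp_needed)],
    effect_allele = ifelse(flip, snps$ref[seq_len(n_snp_needed)],
                           snps$alt[seq_len(n_snp_needed)]),
    other_allele = ifelse(flip, snps$alt[seq_len(n_snp_needed)],
                          snps$ref[seq_len(n_snp_needed)]),
    weight = rnorm(n_snp_needed, 0, weight_scale)
  )
  # training R2 with median near 0.19, the typical scale of sparse cis models
  summary <- tibble::tibble(
    gene_id = gene_id,
    tissue = "SyntheticTissue",
    training_r2 = stats::rbeta(n_genes, 1.1, 4.5)
  )

  selection_map <- setNames(rep(0, nrow(snps)), snps$snp_id)
  sel_tbl <- tibble::tibble(gene_id = character(), direction = numeric(),
                            s = numeric())
  if (!is.null(selected_genes) && nrow(selected_genes) > 0) {
    selected_genes <- tibble::as_tibble(selected_genes)
    if (!"s" %in% names(selected_genes)) selected_genes$s <- 0.02
    for (k in seq_len(nrow(selected_genes))) {
      gi <- selected_genes$gene[k]
      dir_k <- selected_genes$direction[k]
      s_k <- selected_genes$s[k]
      idx <- starts[gi]:ends[gi]
      w <- weights$weight[idx]
      if (all(w == 0)) abort("selected gene has a zero-weight model")
      # s on the effect-allele scale, then mapped to the alt-allele scale
      s_eff <- dir_k * sign(w) * s_k
      is_alt <- weights$effect_allele[idx] == snps$alt[idx]
      selection_map[weights$snp_id[idx]] <- ifelse(is_alt, s_eff, -s_eff)
      sel_tbl <- dplyr::bind_rows(sel_tbl, tibble::tibble(
        gene_id = gene_id[gi], direction = dir_k, s = s_k))
    }
  }
  list(
    weights = weights,
    summary = summary,
    architecture = list(selection_map = selection_map, selected = sel_tbl,
                        snps = snps)
  )
}

#' Simulate per-SNP normalized selection scores (SDS/iHS stand-ins)
#'
#' Scores are standard normal at neutral SNPs and shifted by
#' `shift_per_unit_s * s` at selected SNPs, emulating genome-wide normalized
#' haplotype statistics. A configurable fraction of SNPs is masked (no
#' score), and a fraction of scores is reported for the ref rather than the
#' alt allele (with the sign negated accordingly), exercising downstream
#' polarity handling.
#'
#' @param snps SNP tibble with `snp_id`, `ref`, `alt`.
#' @param true_s Named numeric vector of alt-allele selection coefficients
#'   (defaults to 0 for SNPs not named).
#' @param shift_per_unit_s Mean score shift per unit of s.
#' @param mask_fraction Fraction of SNPs left without a score.
#' @param flip_fraction Fraction of scores reported for the ref allele.
#' @param seed Optional integer seed.
#' @return Tibble `snp_id`, `allele`, `score`.
#' @export
simulate_classic_scores <- function(snps, true_s = NULL,
                                    shift_per_unit_s = 100,
                                    mask_fraction = 0,
                                    flip_fraction = 0,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.finite(shift_per_unit_s)) abort("shift_per_unit_s must be finite")
  snps <- tibble::as_tibble(snps)
  s <- setNames(rep(0, nrow(snps)), snps$snp_id)
  if (!is.null(true_s)) s[names(true_s)] <- true_s
  score <- rnorm(nrow(snps), shift_per_unit_s * s, 1)
  flip <- runif(nrow(snps)) < flip_fraction
  out <- tibble::tibble(
    snp_id = snps$snp_id,
    allele = ifelse(flip, snps$ref, snps$alt),
    score = ifelse(flip, -score, score)
  )
  if (mask_fraction > 0) {
    keep <- runif(nrow(out)) >= mask_fraction
    out <- out[keep, ]
  }
  out
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining [simulate_gene_models()],
#' [simulate_trajectories][simulate_trajectory],
#' [simulate_cohort()] and [simulate_classic_scores()]: a dated cohort drawn
#' from Wright-Fisher trajectories, sparse eQTL models over contiguous SNP
#' blocks, and per-SNP selection scores, all from one seed.
#'
#' @param n_genes Number of modeled genes.
#' @param config A [sim_config()]; its seed drives all stages.
#' @param selected_genes Passed to [simulate_gene_models()].
#' @param snps_per_gene Passed to [simulate_gene_models()].
#' @param initial_freq_range Range of initial allele frequencies.
#' @param score_shift,score_mask_fraction Passed to
#'   [simulate_classic_scores()].
#' @param flip_fraction Passed to [simulate_gene_models()].
#' @return List: `dataset`, `samples`, `weights`, `summary`, `scores`,
#'   `architecture`, `trajectories`, `config`.
#' @export
simulate_study <- function(n_genes = 150,
                           config = sim_config(),
                           selected_genes = NULL,
                           snps_per_gene = NULL,
                           initial_freq_range = c(0.05, 0.95),
                           score_shift = 100,
                           score_mask_fraction = 0.2,
                           flip_fraction = 0.2) {
  set.seed(config$seed)
  mods <- simulate_gene_models(
    n_genes, snps_per_gene = snps_per_gene,
    selected_genes = selected_genes, flip_fraction = flip_fraction
  )
  snps <- mods$architecture$snps
  snps$chrom <- "1"
  snps$pos <- 5000L * seq_len(nrow(snps))
  p0 <- runif(nrow(snps), initial_freq_range[1], initial_freq_range[2])
  s <- mods$architecture$selection_map[snps$snp_id]
  traj <- simulate_trajectories(p0, s, config$n_generations,
                                config$effective_population_size)
  colnames(traj) <- snps$snp_id
  cohort <- simulate_cohort(config, traj, snps = snps)
  scores <- simulate_classic_scores(
    snps, true_s = mods$architecture$selection_map,
    shift_per_unit_s = score_shift, mask_fraction = score_mask_fraction,
    flip_fraction = flip_fraction, seed = config$seed + 2L
  )
  list(
    dataset = cohort$dataset,
    samples = cohort$samples,
    weights = mods$weights,
    summary = mods$summary,
    scores = scores,
    architecture = mods$architecture,
    trajectories = traj,
    config = config
  )
}
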