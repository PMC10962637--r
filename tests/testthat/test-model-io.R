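test_that("VCF GT genotypes become alt-allele counts", {
  f <- withr::local_tempfile(fileext = ".vcf")
  rows <- c(
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/0\t./.",
    "1\t300\trs3\tA\tC\t.\tPASS\t.\tGT\t0|1\t1|1"
  )
  write_gt_vcf(f, rows, c("sampleA", "sampleB"))
  ds <- load_genotypes(f)
  expect_equal(unname(ds$dosages["sampleA", c("rs1", "rs2", "rs3")]),
               c(1, 0, 1))
  expect_equal(unname(ds$dosages["sampleB", "rs1"]), 2)
  expect_true(is.na(ds$dosages["sampleB", "rs2"]))
  expect_equal(ds$snps$imputation_r2, rep(1, 3))
})

test_that("VCF DS dosages and R2 INFO are read verbatim", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"q\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"d\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "1\t100\trs1\tA\tG\t.\tPASS\tR2=0.87\tDS\t1.73"
  ), f)
  ds <- load_genotypes(f)
  expect_equal(unname(ds$dosages["s1", "rs1"]), 1.73)
  expect_equal(ds$snps$imputation_r2, 0.87)
})

test_that("write -> read round-trips reproduce the dataset exactly", {
  cfg <- sim_config(seed = 31, sample_schedule = tibble::tibble(
    date_bp = c(3000, 0), n = c(8, 8)))
  traj <- twasscan:::simulate_trajectories(runif(25, 0.1, 0.9), 0,
                                           cfg$n_generations, 1e3)
  ds <- simulate_cohort(cfg, traj)$dataset
  for (ext in c(".vcf", ".tsv")) {
    f <- withr::local_tempfile(fileext = ext)
    write_genotypes(ds, f)
    back <- load_genotypes(f)
    expect_equal(back$dosages, ds$dosages, tolerance = 0)
    expect_equal(back$snps$imputation_r2, ds$snps$imputation_r2,
                 tolerance = 0)
    expect_equal(back$snps$pos, ds$snps$pos)
  }
})

test_that("duplicate sites are rejected", {
  f <- withr::local_tempfile(fileext = ".vcf")
  rows <- rep("1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1", 2)
  write_gt_vcf(f, rows, "s1")
  expect_error(load_genotypes(f), "duplicate|non-unique")
})

test_that("loading is order-independent after canonical sorting", {
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  rows <- c(
    "2\t100\trs3\tA\tG\t.\tPASS\t.\tGT\t0/1",
    "1\t500\trs2\tC\tT\t.\tPASS\t.\tGT\t1/1",
    "1\t100\trs1\tA\tC\t.\tPASS\t.\tGT\t0/0"
  )
  write_gt_vcf(f1, rows, "s1")
  write_gt_vcf(f2, rev(rows), "s1")
  a <- load_genotypes(f1)
  b <- load_genotypes(f2)
  expect_identical(a$snps, b$snps)
  expect_identical(a$dosages, b$dosages)
  expect_equal(a$snps$snp_id, c("rs1", "rs2", "rs3"))
})

test_that("best-tissue selection keeps the highest training R2, ties by name", {
  w <- tibble::tibble(
    gene_id = "g1", tissue = c("Brain", "Liver", "Lung"),
    snp_id = "s1", effect_allele = "G", other_allele = "A", weight = 0.5
  )
  s <- tibble::tibble(gene_id = "g1", tissue = c("Brain", "Liver", "Lung"),
                      training_r2 = c(0.1, 0.5, 0.3))
  m <- gene_models(w, s)
  expect_equal(unique(m$tissue), "Liver")
  expect_equal(unique(m$training_r2), 0.5)

  s_tie <- tibble::tibble(gene_id = "g1", tissue = c("Lung", "Liver"),
                          training_r2 = c(0.4, 0.4))
  m_tie <- gene_models(w[w$tissue != "Brain", ], s_tie)
  expect_equal(unique(m_tie$tissue), "Liver")
})

test_that("model table validation catches bad input", {
  w <- tibble::tibble(gene_id = "g1", tissue = "T", snp_id = "s1",
                      effect_allele = "G", other_allele = "A", weight = 0.5)
  s_neg <- tibble::tibble(gene_id = "g1", tissue = "T", training_r2 = -0.1)
  expect_error(gene_models(w, s_neg), "negative")
  s_missing <- tibble::tibble(gene_id = "g2", tissue = "T", training_r2 = 0.2)
  expect_error(gene_models(w, s_missing), "absent from summary")
  s_extra <- tibble::tibble(gene_id = c("g1", "g3"), tissue = "T",
                            training_r2 = c(0.2, 0.2))
  expect_warning(gene_models(w, s_extra), "no variants")
})

test_that("model summary reports sizes; median over {3,12,40} is 12", {
  sizes <- c(3, 12, 40)
  w <- purrr::map_dfr(seq_along(sizes), function(i) tibble::tibble(
    gene_id = paste0("g", i), tissue = "T",
    snp_id = paste0("g", i, "_s", seq_len(sizes[i])),
    effect_allele = "G", other_allele = "A", weight = 1))
  s <- tibble::tibble(gene_id = paste0("g", 1:3), tissue = "T",
                      training_r2 = 0.3)
  ms <- model_summary(gene_models(w, s))
  expect_equal(median(ms$n_snps), 12)
})

test_that("gene model TSV round-trip preserves content", {
  m <- simulate_gene_models(4, snps_per_gene = 5, seed = 17)
  mods <- gene_models(m$weights, m$summary)
  wf <- withr::local_tempfile(fileext = ".tsv")
  sf <- withr::local_tempfile(fileext = ".tsv")
  write_gene_models(mods, wf, sf)
  back <- load_gene_models(wf, sf)
  expect_equal(back$weight, mods$weight)
  expect_equal(back$gene_id, mods$gene_id)
  expect_equal(back$training_r2, mods$training_r2)
})

test_that("allele orientation flips ref-effect variants and flags the rest", {
  dos <- matrix(c(0.5, 1.2), nrow = 1)
  ds <- tiny_dataset(dos, ref = c("A", "A"), alt = c("G", "T"))
  m <- tibble::tibble(
    gene_id = "g1", tissue = "T", training_r2 = 0.5,
    snp_id = c("s1", "s1", "s2", "s2"),
    effect_allele = c("A", "G", "T", "C"),
    other_allele = c("G", "A", "A", "G"),
    weight = 1
  )
  al <- align_alleles(m, ds, quiet = TRUE)
  expect_equal(al$flip, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(al$resolvable, c(TRUE, TRUE, TRUE, FALSE))
  # s2 is an A/T site: resolvable by allele match but flagged ambiguous
  expect_equal(al$ambiguous, c(FALSE, FALSE, TRUE, FALSE))
  od <- oriented_dosages(al[1, ], ds)
  expect_equal(unname(od[1, 1]), 1.5)
  od2 <- oriented_dosages(al[2, ], ds)
  expect_equal(unname(od2[1, 1]), 0.5)
})

test_that("orientation is an involution", {
  dos <- matrix(runif(10, 0, 2), nrow = 2)
  ds <- tiny_dataset(dos)
  m <- tiny_model(ds$snps$snp_id, weights = rep(1, 5), effect = "A",
                  other = "G")
  al <- align_alleles(m, ds, quiet = TRUE)
  once <- oriented_dosages(al, ds)
  # flipping the already-flipped doses reproduces the raw matrix
  expect_equal(2 - once, unname(ds$dosages), ignore_attr = TRUE)
})

test_that("site filters subset a loaded dataset", {
  cfg <- sim_config(seed = 41, sample_schedule = tibble::tibble(
    date_bp = 0, n = 5))
  traj <- twasscan:::simulate_trajectories(runif(10, 0.2, 0.8), 0,
                                           cfg$n_generations, 1e3)
  ds <- simulate_cohort(cfg, traj)$dataset
  f <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes(ds, f)
  ids <- ds$snps$snp_id[c(2, 5)]
  sub <- load_genotypes(f, site_filter = ids)
  expect_equal(sub$snps$snp_id, ids)
  reg <- load_genotypes(f, site_filter = tibble::tibble(
    chrom = "1", start = 1, end = ds$snps$pos[3]))
  expect_equal(nrow(reg$snps), 3)
})
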